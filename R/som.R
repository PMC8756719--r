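#' Initialize a self-organizing map lattice
#'
#' Creates an H x W grid of weight vectors in latent space, initialized
#' uniformly in `[0, 1)`. Nodes are stored row-major: node index
#' `row * W + col + 1` with zero-based `(row, col)` coordinates.
#'
#' @param som_dim `c(H, W)` grid dimensions (default `c(15, 15)`).
#' @param latent_dim weight dimensionality (the autoencoder latent width).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return An object of class `som_lattice`: list with `H`, `W`, `weights`
#'   (nodes x latent_dim), `coords` (nodes x 2, zero-based) and `grid_d2`
#'   (precomputed squared grid distances between nodes).
#' @export
som_lattice <- function(som_dim = c(15, 15), latent_dim, seed = NULL) {
  if (length(som_dim) != 2 || any(som_dim < 1)) {
    stop_input("`som_dim` must be c(H, W) with H, W >= 1")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  H <- as.integer(som_dim[1]); W <- as.integer(som_dim[2])
  n_nodes <- H * W
  coords <- cbind(row = rep(seq_len(H) - 1L, each = W),
                  col = rep(seq_len(W) - 1L, times = H))
  grid_d2 <- outer(coords[, 1], coords[, 1], `-`)^2 +
    outer(coords[, 2], coords[, 2], `-`)^2
  structure(list(H = H, W = W,
                 weights = matrix(stats::runif(n_nodes * latent_dim),
                                  n_nodes, latent_dim),
                 coords = coords, grid_d2 = grid_d2),
            class = "som_lattice")
}

#' @export
print.som_lattice <- function(x, ...) {
  cat(sprintf("som_lattice: %d x %d grid, %d-dimensional weights\n",
              x$H, x$W, ncol(x$weights)))
  invisible(x)
}

#' Best matching unit for one latent vector
#'
#' Returns the node whose weight vector is Euclidean-closest to `z` (the
#' winning node). Ties are broken deterministically by the smallest
#' row-major node index.
#'
#' @param lattice a `som_lattice`.
#' @param z latent vector of the lattice's weight dimension.
#' @return List with zero-based `row`, `col`, the 1-based row-major `index`,
#'   and `distance`.
#' @export
find_bmu <- function(lattice, z) {
  if (length(z) != ncol(lattice$weights)) {
    stop_input(sprintf("latent dimension mismatch: lattice has %d, z has %d",
                       ncol(lattice$weights), length(z)))
  }
  d2 <- rowSums(sweep(lattice$weights, 2, z, `-`)^2)
  i <- which.min(d2)
  list(row = unname(lattice$coords[i, 1]), col = unname(lattice$coords[i, 2]),
       index = i, distance = sqrt(unname(d2[i])))
}

# Vectorized BMU search for a latent matrix Z (n x d). Returns list with
# integer vector idx (1-based row-major) and numeric distance.
bmu_indices <- function(lattice, Z) {
  Wt <- lattice$weights
  d2 <- outer(rowSums(Z^2), rep(1, nrow(Wt))) -
    2 * Z %*% t(Wt) +
    outer(rep(1, nrow(Z)), rowSums(Wt^2))
  idx <- max.col(-d2, ties.method = "first")
  list(idx = idx, distance = sqrt(pmax(d2[cbind(seq_len(nrow(Z)), idx)], 0)))
}

# Mean distance of latent vectors to their BMU weights.
quantization_error <- function(lattice, Z) mean(bmu_indices(lattice, Z)$distance)

#' One batch of self-organizing map updates
#'
#' For every latent vector in the batch, each node `(i, j)` moves by
#' `eta * h * (z - w_ij)` where `h = exp(-d_grid^2 / (2 sigma^2))` is the
#' Gaussian neighbourhood kernel around the winning node. Contributions
#' from the batch are accumulated against the batch-start weights and
#' applied together.
#'
#' @param lattice a `som_lattice`.
#' @param Z latent batch (n x latent_dim matrix, or a single vector).
#' @param eta learning rate.
#' @param sigma Gaussian neighbourhood width (> 0), in grid units.
#' @return The updated `som_lattice`.
#' @export
som_update_batch <- function(lattice, Z, eta, sigma) {
  if (sigma <= 0) stop_input("`sigma` must be > 0")
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  if (eta == 0) return(lattice)
  bmu <- bmu_indices(lattice, Z)
  # Hm[node, sample] = neighbourhood weight of `node` for that sample's BMU.
  Hm <- exp(-lattice$grid_d2[, bmu$idx, drop = FALSE] / (2 * sigma^2))
  lattice$weights <- lattice$weights +
    eta * (Hm %*% Z - rowSums(Hm) * lattice$weights)
  lattice
}

# Exponentially decaying neighbourhood width: sigma0 * exp(-t / tau) with
# tau = T / log(sigma0 / sigma_end), so sigma reaches sigma_end at the final
# epoch. Epochs are 0-based here.
sigma_schedule <- function(t, total, sigma0, sigma_end = 0.5) {
  if (sigma0 <= sigma_end) return(rep(sigma0, length(t)))
  sigma0 * exp(-t / (total / log(sigma0 / sigma_end)))
}

#' Pre-train the self-organizing map on a latent embedding
#'
#' Runs batched SOM updates over shuffled mini-batches for `epochs` passes,
#' under a time-decaying Gaussian neighbourhood: `sigma(t) = sigma0 *
#' exp(-t / tau)` with `sigma0 = max(H, W) / 2` and `tau = epochs /
#' log(sigma0 / sigma_end)`, so the neighbourhood starts wide (global
#' ordering) and shrinks to `sigma_end` grid units (local refinement; on
#' small lattices an end width below one grid unit lets individual nodes
#' specialize to separated clusters). The autoencoder is not touched
#' during this phase.
#'
#' @param lattice a `som_lattice`.
#' @param Z latent matrix (n x latent_dim).
#' @param epochs number of passes (default 1500 at full scale).
#' @param batch_size mini-batch size (default 64).
#' @param eta learning rate (default 0.005).
#' @param sigma0 initial neighbourhood width; default `max(H, W) / 2`.
#' @param sigma_end final neighbourhood width (default 0.5).
#' @return List with the trained `lattice` and `qe_history`: the
#'   quantization error (mean BMU distance over `Z`) before training and
#'   after every epoch (`epochs + 1` values).
#' @export
pretrain_som <- function(lattice, Z, epochs, batch_size = 64, eta = 0.005,
                         sigma0 = NULL, sigma_end = 0.5) {
  if (epochs < 1) stop_input("`epochs` must be >= 1")
  sigma0 <- sigma0 %||% (max(lattice$H, lattice$W) / 2)
  qe <- numeric(epochs + 1)
  qe[1] <- quantization_error(lattice, Z)
  for (ep in seq_len(epochs)) {
    sigma <- sigma_schedule(ep - 1, epochs, sigma0, sigma_end)
    for (batch in make_batches(nrow(Z), batch_size)) {
      lattice <- som_update_batch(lattice, Z[batch, , drop = FALSE], eta, sigma)
    }
    qe[ep + 1] <- quantization_error(lattice, Z)
  }
  list(lattice = lattice, qe_history = qe)
}
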