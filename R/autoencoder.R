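#' Build a symmetric autoencoder with geometric-series widths
#'
#' Layer widths form a geometric series from `input_dim` down to
#' `latent_dim`: width k is `round(input_dim * r^k)` with
#' `r = (latent_dim / input_dim)^(1 / (n_encoder_layers - 1))`. The decoder
#' mirrors the encoder exactly. Weights are initialized uniformly on
#' `(-0.5, 0.5)` scaled by `1 / sqrt(fan_in)` (centered uniform; an
#' all-positive draw makes the first hidden layer's outputs nearly
#' collinear and the reconstruction collapses to the feature means);
#' biases start at zero. Hidden
#' layers (including the latent layer) use the configured activation; the
#' final reconstruction layer is linear.
#'
#' @param input_dim number of input features.
#' @param latent_dim latent width (default 25).
#' @param n_encoder_layers number of encoder widths including input and
#'   latent (default 3, i.e. one hidden layer).
#' @param activation one of `"tanh"` (default), `"relu"`, `"sigmoid"`,
#'   `"linear"`.
#' @param l2_strength L2 penalty coefficient on the weights (default 1e-4).
#' @param seed optional integer seed for the initialization draw; `NULL`
#'   uses the current RNG state.
#' @return An object of class `autoencoder`.
#' @examples
#' ae <- build_autoencoder(984, 25, seed = 1)
#' ae$widths  # 984 157 25
#' @export
build_autoencoder <- function(input_dim, latent_dim = 25,
                              n_encoder_layers = 3,
                              activation = c("tanh", "relu", "sigmoid", "linear"),
                              l2_strength = 1e-4, seed = NULL) {
  activation <- match.arg(activation)
  if (latent_dim >= input_dim) stop_input("`latent_dim` must be < `input_dim`")
  if (latent_dim < 1) stop_input("`latent_dim` must be >= 1")
  if (n_encoder_layers < 2) stop_input("`n_encoder_layers` must be >= 2")
  if (!is.null(seed)) set.seed(as.integer(seed))

  r <- (latent_dim / input_dim)^(1 / (n_encoder_layers - 1))
  widths <- round(input_dim * r^(seq_len(n_encoder_layers) - 1))
  widths[1] <- input_dim
  widths[n_encoder_layers] <- latent_dim
  widths <- pmax(widths, latent_dim)

  full <- c(widths, rev(widths)[-1])
  layers <- vector("list", length(full) - 1)
  for (l in seq_along(layers)) {
    fan_in <- full[l]
    layers[[l]] <- list(
      W = matrix((stats::runif(fan_in * full[l + 1]) - 0.5) / sqrt(fan_in),
                 fan_in, full[l + 1]),
      b = numeric(full[l + 1])
    )
  }
  structure(list(widths = widths, layer_sizes = full, params = layers,
                 n_encoder = n_encoder_layers - 1,
                 activation = activation, l2_strength = l2_strength),
            class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("autoencoder: %s (%s hidden activation, linear output)\n",
              paste(x$layer_sizes, collapse = " - "), x$activation))
  invisible(x)
}

act_fun <- function(x, name) {
  switch(name,
         tanh = tanh(x),
         relu = pmax(x, 0),
         sigmoid = 1 / (1 + exp(-x)),
         linear = x)
}

# Derivative expressed through the activation value a = f(x).
act_grad <- function(a, name) {
  switch(name,
         tanh = 1 - a^2,
         relu = (a > 0) * 1,
         sigmoid = a * (1 - a),
         linear = array(1, dim(a) %||% length(a)))
}

# Forward pass through all layers; returns the list of activations
# A[[1]] = X .. A[[L+1]] = reconstruction. The last layer is linear.
ae_forward <- function(ae, X) {
  L <- length(ae$params)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% ae$params[[l]]$W
    Z <- sweep(Z, 2, ae$params[[l]]$b, `+`)
    A[[l + 1]] <- if (l == L) Z else act_fun(Z, ae$activation)
  }
  A
}

#' Encode samples to the latent space
#'
#' Deterministic forward pass through the encoder half of the autoencoder.
#'
#' @param ae an `autoencoder`.
#' @param x an `expr_matrix` or numeric matrix whose columns match the
#'   autoencoder input width. Inputs are used as given; callers are
#'   responsible for applying the same feature scaling used in training
#'   (the [dnm()] interface does this automatically).
#' @return An n x latent_dim matrix.
#' @export
encode <- function(ae, x) {
  X <- if (inherits(x, "expr_matrix")) x$values else x
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != ae$layer_sizes[1]) {
    stop_input(sprintf("feature mismatch: autoencoder expects %d inputs, got %d",
                       ae$layer_sizes[1], ncol(X)))
  }
  for (l in seq_len(ae$n_encoder)) {
    Z <- X %*% ae$params[[l]]$W
    Z <- sweep(Z, 2, ae$params[[l]]$b, `+`)
    X <- act_fun(Z, ae$activation)
  }
  X
}

#' Reconstruct samples through the full autoencoder
#' @inheritParams encode
#' @return An n x input_dim matrix of reconstructions.
#' @export
reconstruct <- function(ae, x) {
  X <- if (inherits(x, "expr_matrix")) x$values else x
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  A <- ae_forward(ae, X)
  A[[length(A)]]
}

# Loss and gradients for a batch. The loss is
#   mean((X - Xhat)^2) + l2 * sum(W^2) + lambda * mean_i ||z_i - w_bmu(i)||^2
# where the BMU weight rows Wbmu are treated as constants (no gradient
# through the argmin). Returns list(loss, grads) with grads matching the
# params structure.
ae_grad <- function(ae, X, lambda = 0, Wbmu = NULL) {
  L <- length(ae$params)
  n <- nrow(X)
  A <- ae_forward(ae, X)
  Xhat <- A[[L + 1]]
  err <- Xhat - X
  loss <- mean(err^2)
  l2 <- ae$l2_strength
  if (l2 > 0) loss <- loss + l2 * sum(vapply(ae$params, function(p) sum(p$W^2), 0))

  latent_idx <- ae$n_encoder + 1  # activation index of the latent layer
  delta <- 2 * err / (n * ncol(X))
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(A[[l]], delta) + 2 * l2 * ae$params[[l]]$W,
                       b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(ae$params[[l]]$W)
      if (lambda > 0 && l == latent_idx) {
        # Joint term enters at the latent activation: d/dz lambda*||z - w||^2.
        dz <- A[[latent_idx]] - Wbmu
        loss <- loss + lambda * sum(dz^2) / n
        delta <- delta + (2 * lambda / n) * dz
      }
      delta <- delta * act_grad(A[[l]], ae$activation)
    }
  }
  if (!is.finite(loss)) stop_numeric("non-finite autoencoder loss")
  list(loss = loss, grads = grads)
}

# --- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in seq_along(params)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[l]]$W <- params[[l]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params[[l]]$b <- params[[l]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[l]] <- s
  }
  list(params = params, state = state)
}

#' Pre-train the autoencoder
#'
#' Minimizes mean squared reconstruction error plus the L2 weight penalty by
#' mini-batch gradient descent with Adam. Batches are reshuffled every
#' epoch using the current RNG state, so runs are deterministic after
#' `set.seed()`.
#'
#' @param ae an `autoencoder`.
#' @param x training matrix (samples x features), already feature-scaled.
#' @param epochs number of passes over the data.
#' @param batch_size mini-batch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @return List with the trained `ae` and `loss_history` (one mean batch
#'   loss per epoch).
#' @export
pretrain_autoencoder <- function(ae, x, epochs, batch_size = 64, lr = 1e-3) {
  X <- if (inherits(x, "expr_matrix")) x$values else x
  if (epochs < 1) stop_input("`epochs` must be >= 1")
  state <- adam_init(ae$params)
  t <- 0L
  loss_history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    batches <- make_batches(nrow(X), batch_size)
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      g <- ae_grad(ae, X[batches[[bi]], , drop = FALSE])
      t <- t + 1L
      upd <- adam_step(ae$params, g$grads, state, t, lr)
      ae$params <- upd$params
      state <- upd$state
      losses[bi] <- g$loss
    }
    loss_history[ep] <- mean(losses)
  }
  list(ae = ae, loss_history = loss_history)
}

# --- Min-max feature scaler -------------------------------------------------

scaler_fit <- function(X) {
  mn <- apply(X, 2, min)
  rg <- apply(X, 2, max) - mn
  rg[rg == 0] <- 1
  list(min = mn, range = rg)
}

scaler_apply <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$min, `-`), 2, scaler$range, `/`)
}
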