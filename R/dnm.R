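#' Jointly fine-tune the autoencoder and the self-organizing map
#'
#' After both components are pre-trained, the autoencoder loss gains a
#' topology term: reconstruction MSE + L2 penalty + `lambda *
#' ||z - w_bmu||^2`, where `w_bmu` is the weight of each sample's winning
#' node. The winning node and its weight are treated as constants within
#' each optimizer step (no gradient flows through the argmin). After every
#' autoencoder step, SOM weights are updated from the same batch's latent
#' vectors with the usual neighbourhood rule, under a narrow neighbourhood
#' that decays from 1 to 0.1 grid units over the phase.
#'
#' @param ae a pre-trained `autoencoder`.
#' @param lattice a pre-trained `som_lattice`.
#' @param x training matrix (samples x features), feature-scaled.
#' @param epochs number of joint passes (default 1250 at full scale).
#' @param batch_size mini-batch size (default 64).
#' @param ae_lr Adam learning rate for the autoencoder (default 2e-3).
#' @param som_lr SOM learning rate during this phase (default 0.002,
#'   smaller than in pre-training so the learned topology stays stable
#'   while the latent space moves).
#' @param lambda weight of the winning-node distance term (default 0.1).
#' @return List with the fine-tuned `ae`, `lattice`, and `loss_history`
#'   (combined loss per epoch).
#' @export
joint_finetune <- function(ae, lattice, x, epochs, batch_size = 64,
                           ae_lr = 2e-3, som_lr = 0.002, lambda = 0.1) {
  X <- if (inherits(x, "expr_matrix")) x$values else x
  if (epochs < 1) stop_input("`epochs` must be >= 1")
  state <- adam_init(ae$params)
  t <- 0L
  loss_history <- numeric(epochs)
  sigma_min <- 0.1
  for (ep in seq_len(epochs)) {
    sigma <- max(sigma_min, exp(-(ep - 1) / (epochs / log(1 / sigma_min))))
    batches <- make_batches(nrow(X), batch_size)
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      Xb <- X[batches[[bi]], , drop = FALSE]
      Z <- encode(ae, Xb)
      if (lambda > 0) {
        bmu <- bmu_indices(lattice, Z)
        Wbmu <- lattice$weights[bmu$idx, , drop = FALSE]
      } else {
        Wbmu <- NULL
      }
      g <- ae_grad(ae, Xb, lambda = lambda, Wbmu = Wbmu)
      t <- t + 1L
      upd <- adam_step(ae$params, g$grads, state, t, ae_lr)
      ae$params <- upd$params
      state <- upd$state
      if (som_lr > 0) {
        lattice <- som_update_batch(lattice, Z, som_lr, sigma)
      }
      losses[bi] <- g$loss
    }
    loss_history[ep] <- mean(losses)
  }
  list(ae = ae, lattice = lattice, loss_history = loss_history)
}

#' Fit a Deep Neural Map
#'
#' Trains the full model in the three phases of the Deep Neural Map:
#' autoencoder pre-training (reconstruction + L2 loss, Adam), SOM
#' pre-training on the frozen latent embedding (decaying Gaussian
#' neighbourhood), and joint fine-tuning under the combined reconstruction
#' plus winning-node distance loss. Features are min-max scaled to
#' `[0, 1]` internally; the scaler is fitted on the training data and
#' stored so [predict.dnm()] applies the identical transform to new data.
#'
#' The epoch defaults (3500 / 1500 / 1250) are the full-scale settings for
#' an atlas-sized cohort; reduce them for small cohorts and examples.
#'
#' @param x training data: a normalized `expr_matrix` or a numeric matrix
#'   (samples x features) with row and column names.
#' @param latent_dim autoencoder latent width (default 25).
#' @param n_encoder_layers encoder widths including input and latent
#'   (default 3).
#' @param som_dim SOM grid `c(H, W)` (default `c(15, 15)`).
#' @param activation hidden activation (default `"tanh"`).
#' @param l2_strength L2 penalty (default 1e-4).
#' @param ae_epochs,som_epochs,joint_epochs phase lengths.
#' @param batch_size mini-batch size for all phases (default 64).
#' @param ae_lr Adam learning rate (default 2e-3).
#' @param som_lr SOM learning rate during pre-training (default 0.005).
#' @param joint_som_lr SOM learning rate during joint fine-tuning
#'   (default 0.002).
#' @param lambda winning-node distance weight in the joint loss
#'   (default 0.1).
#' @param sigma_end final neighbourhood width of SOM pre-training
#'   (default 0.5).
#' @param seed integer seed controlling initialization and batch order; a
#'   fixed seed makes the whole fit bit-reproducible.
#' @return An object of class `dnm`: list with `autoencoder`, `som`,
#'   `scaler`, `features`, `history` (`ae`, `som_qe`, `joint`),
#'   `train_assignment` (BMU assignment of the training samples), `config`
#'   and `call`.
#' @seealso [predict.dnm()], [label_nodes()], [classify_samples()],
#'   [class_average_activation()]
#' @export
dnm <- function(x, latent_dim = 25, n_encoder_layers = 3,
                som_dim = c(15, 15),
                activation = "tanh", l2_strength = 1e-4,
                ae_epochs = 3500, som_epochs = 1500, joint_epochs = 1250,
                batch_size = 64, ae_lr = 2e-3, som_lr = 0.005,
                joint_som_lr = 0.002, lambda = 0.1, sigma_end = 0.5,
                seed = 1L) {
  X <- if (inherits(x, "expr_matrix")) x$values else x
  if (is.null(rownames(X)) || is.null(colnames(X))) {
    stop_input("training matrix needs sample row names and feature column names")
  }
  set.seed(as.integer(seed))
  scaler <- scaler_fit(X)
  Xs <- scaler_apply(scaler, X)

  ae <- build_autoencoder(ncol(X), latent_dim, n_encoder_layers,
                          activation = activation, l2_strength = l2_strength)
  pre <- pretrain_autoencoder(ae, Xs, ae_epochs, batch_size, ae_lr)
  ae <- pre$ae

  Z <- encode(ae, Xs)
  lattice <- som_lattice(som_dim, latent_dim)
  som <- pretrain_som(lattice, Z, som_epochs, batch_size, som_lr,
                      sigma_end = sigma_end)
  lattice <- som$lattice

  joint <- joint_finetune(ae, lattice, Xs, joint_epochs, batch_size,
                          ae_lr, joint_som_lr, lambda)

  model <- structure(list(
    autoencoder = joint$ae,
    som = joint$lattice,
    scaler = scaler,
    features = colnames(X),
    history = list(ae = pre$loss_history, som_qe = som$qe_history,
                   joint = joint$loss_history),
    config = list(latent_dim = latent_dim, n_encoder_layers = n_encoder_layers,
                  som_dim = c(lattice$H, lattice$W), activation = activation,
                  l2_strength = l2_strength, ae_epochs = ae_epochs,
                  som_epochs = som_epochs, joint_epochs = joint_epochs,
                  batch_size = batch_size, ae_lr = ae_lr, som_lr = som_lr,
                  joint_som_lr = joint_som_lr, lambda = lambda,
                  sigma_end = sigma_end, seed = as.integer(seed)),
    call = match.call()), class = "dnm")
  model$train_assignment <- map_samples(model, X)
  model
}

#' Map samples to their winning nodes
#'
#' Encodes samples with the trained autoencoder (after applying the stored
#' feature scaler) and assigns each to its best matching unit.
#'
#' @param model a fitted `dnm`.
#' @param x an `expr_matrix` or matrix on the same feature axis as the
#'   training data (unscaled; the model's scaler is applied).
#' @return A data frame of class `bmu_assignment` with columns `sample_id`,
#'   `row`, `col` (zero-based lattice coordinates) and `distance`, plus
#'   attribute `"som_dim"`.
#' @export
map_samples <- function(model, x) {
  X <- if (inherits(x, "expr_matrix")) x$values else x
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (!identical(colnames(X), model$features)) {
    if (is.null(colnames(X)) || !setequal(colnames(X), model$features)) {
      stop_input(sprintf(
        "feature mismatch: model was trained on %d features; input has %d",
        length(model$features), ncol(X)))
    }
    X <- X[, model$features, drop = FALSE]
  }
  Z <- encode(model$autoencoder, scaler_apply(model$scaler, X))
  bmu <- bmu_indices(model$som, Z)
  out <- data.frame(sample_id = rownames(X),
                    row = unname(model$som$coords[bmu$idx, 1]),
                    col = unname(model$som$coords[bmu$idx, 2]),
                    distance = unname(bmu$distance),
                    stringsAsFactors = FALSE)
  attr(out, "som_dim") <- c(model$som$H, model$som$W)
  class(out) <- c("bmu_assignment", "data.frame")
  out
}

#' Predict method for Deep Neural Maps
#'
#' @param object a fitted `dnm`.
#' @param newdata `expr_matrix` or matrix on the training feature axis.
#' @param type `"bmu"` (default) returns the winning-node assignment,
#'   `"latent"` the latent embedding, `"reconstruction"` the decoder output
#'   in scaled feature space.
#' @param ... ignored.
#' @return See `type`.
#' @export
predict.dnm <- function(object, newdata, type = c("bmu", "latent", "reconstruction"),
                        ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "expr_matrix")) newdata$values else newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (type == "bmu") return(map_samples(object, X))
  Xs <- scaler_apply(object$scaler, X)
  switch(type,
         latent = encode(object$autoencoder, Xs),
         reconstruction = reconstruct(object$autoencoder, Xs))
}

#' @export
residuals.dnm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    stop_input("supply `newdata`; the model does not store its training matrix")
  }
  X <- if (inherits(newdata, "expr_matrix")) newdata$values else newdata
  Xs <- scaler_apply(object$scaler, X)
  Xs - reconstruct(object$autoencoder, Xs)
}

#' @export
print.dnm <- function(x, ...) {
  cfg <- x$config
  cat("Deep Neural Map\n")
  cat(sprintf("  autoencoder: %s (%s)\n",
              paste(x$autoencoder$layer_sizes, collapse = " - "),
              cfg$activation))
  cat(sprintf("  SOM lattice: %d x %d\n", x$som$H, x$som$W))
  cat(sprintf("  epochs: AE %d, SOM %d, joint %d; lambda = %g; seed = %d\n",
              cfg$ae_epochs, cfg$som_epochs, cfg$joint_epochs, cfg$lambda,
              cfg$seed))
  cat(sprintf("  final AE loss %.4g; final quantization error %.4g\n",
              utils::tail(x$history$ae, 1),
              mean(x$train_assignment$distance)))
  invisible(x)
}

#' @export
summary.dnm <- function(object, ...) {
  h <- object$history
  out <- list(
    config = object$config,
    ae_loss = c(first = h$ae[1], last = utils::tail(h$ae, 1)),
    som_qe = c(first = h$som_qe[1], last = utils::tail(h$som_qe, 1)),
    joint_loss = c(first = h$joint[1], last = utils::tail(h$joint, 1)),
    train_qe = mean(object$train_assignment$distance),
    occupied_nodes = nrow(unique(object$train_assignment[, c("row", "col")])),
    n_nodes = object$som$H * object$som$W)
  class(out) <- "summary.dnm"
  out
}

#' @export
print.summary.dnm <- function(x, ...) {
  cat("Deep Neural Map fit\n")
  cat(sprintf("  AE loss:    %.4g -> %.4g\n", x$ae_loss[1], x$ae_loss[2]))
  cat(sprintf("  SOM QE:     %.4g -> %.4g (pre-training)\n",
              x$som_qe[1], x$som_qe[2]))
  cat(sprintf("  joint loss: %.4g -> %.4g\n", x$joint_loss[1], x$joint_loss[2]))
  cat(sprintf("  training quantization error: %.4g\n", x$train_qe))
  cat(sprintf("  occupied nodes: %d / %d\n", x$occupied_nodes, x$n_nodes))
  invisible(x)
}

#' Plot a Deep Neural Map
#'
#' Draws the sample-density heatmap of the lattice: the per-node count of
#' mapped samples (training assignment by default, or `newdata`).
#'
#' @param x a fitted `dnm`.
#' @param newdata optional matrix/`expr_matrix` to map and plot instead of
#'   the training samples.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the H x W count matrix.
#' @export
plot.dnm <- function(x, newdata = NULL, main = "sample density", ...) {
  assign <- if (is.null(newdata)) x$train_assignment else map_samples(x, newdata)
  dens <- density_map(assign)
  graphics::image(x = seq_len(ncol(dens)) - 1, y = seq_len(nrow(dens)) - 1,
                  z = t(dens)[, rev(seq_len(nrow(dens))), drop = FALSE],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "SOM column", ylab = "SOM row", main = main, ...)
  invisible(dens)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single RDS archive holding the autoencoder and SOM
#' weights, the feature scaler, the feature axis, configuration, and a
#' schema version.
#'
#' @param model a fitted `dnm`.
#' @param path file path.
#' @return `read_dnm()` returns the `dnm`; `write_dnm()` the path,
#'   invisibly.
#' @export
write_dnm <- function(model, path) {
  stopifnot(inherits(model, "dnm"))
  payload <- unclass(model)
  payload$schema <- 1L
  payload$call <- NULL
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_dnm
#' @export
read_dnm <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$schema, 1L)) stop_input("unknown checkpoint schema")
  payload$schema <- NULL
  structure(payload, class = "dnm")
}
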