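# Shared builders for the test suite. Everything is generated in code;
# the only files used are the committed minimal-fixture TSVs.

toy_matrix <- function(values, ids = NULL, feats = NULL, normalized = FALSE) {
  values <- as.matrix(values)
  rownames(values) <- ids %||% paste0("S", seq_len(nrow(values)))
  colnames(values) <- feats %||% paste0("miR-", seq_len(ncol(values)))
  expression_matrix(values, normalized = normalized)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_ontology <- function(ids, tissue, neoplastic) {
  sample_ontology(data.frame(sample_id = ids, tissue = tissue,
                             neoplastic = neoplastic))
}

# A hand-set linear encoder (one weight layer) for closed-form attribution.
linear_encoder <- function(W, b = NULL) {
  ae <- build_autoencoder(nrow(W), ncol(W), 2, activation = "linear", seed = 1)
  ae$params[[1]]$W <- W
  ae$params[[1]]$b <- b %||% numeric(ncol(W))
  ae
}

# Central finite-difference oracle for the activation-gradient scores:
# sum_j |dz_j/dx_i| estimated column by column.
fd_gradient_scores <- function(ae, x, h = 1e-5) {
  d <- length(x)
  sapply(seq_len(d), function(i) {
    e <- numeric(d); e[i] <- h
    jac_col <- (encode(ae, matrix(x + e, 1)) - encode(ae, matrix(x - e, 1))) /
      (2 * h)
    sum(abs(jac_col))
  })
}

# Three well-separated Gaussian blobs inside the unit cube of latent space.
make_blobs <- function(n_per = 50, d = 5, sd = 0.04, seed = 1) {
  set.seed(seed)
  centers <- rbind(rep(0.2, d),
                   rep(0.8, d),
                   rep(c(0.8, 0.2), length.out = d))
  Z <- do.call(rbind, lapply(1:3, function(k) {
    matrix(stats::rnorm(n_per * d, mean = rep(centers[k, ], each = n_per),
                        sd = sd), n_per, d)
  }))
  list(Z = Z, label = rep(1:3, each = n_per))
}

# One small fitted model on the minimal fixture, shared within a test file.
fit_fixture_model <- function(seed = 11, som_dim = c(4, 4)) {
  fx <- generate_minimal_fixture()
  pp <- preprocess_pipeline(fx$expression, fx$ontology, min_class_size = 5,
                            seed = seed)
  model <- dnm(pp$expression[pp$split$train_ids, ], som_dim = som_dim,
               ae_epochs = 120, som_epochs = 80, joint_epochs = 50,
               batch_size = 16, seed = seed)
  list(fx = fx, pp = pp, model = model)
}
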