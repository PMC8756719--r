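test_that("linear encoders give the absolute weight-sum closed form exactly", {
  set.seed(10)
  W <- matrix(rnorm(6 * 3), 6, 3)
  ae <- linear_encoder(W)
  prof <- activation_gradient(ae, runif(6))
  expect_equal(as.numeric(prof), unname(rowSums(abs(W))))

  # deeper linear encoder: product of weight matrices
  ae2 <- build_autoencoder(5, 2, 3, activation = "linear", seed = 10)
  J <- ae2$params[[1]]$W %*% ae2$params[[2]]$W
  prof2 <- activation_gradient(ae2, runif(5))
  expect_equal(as.numeric(prof2), unname(rowSums(abs(J))))

  # all-zero encoder weights: all scores zero
  ae0 <- linear_encoder(matrix(0, 4, 2))
  expect_equal(as.numeric(activation_gradient(ae0, runif(4))),
               rep(0, 4))
})

test_that("analytic scores match central finite differences on tanh encoders", {
  set.seed(11)
  for (trial in 1:25) {
    d <- sample(3:10, 1)
    latent <- sample(1:(d - 1), 1)
    layers <- sample(2:3, 1)
    ae <- build_autoencoder(d, latent, layers, activation = "tanh")
    x <- runif(d)
    analytic <- unclass(activation_gradient(ae, x))
    fd <- fd_gradient_scores(ae, x)
    expect_lt(max(abs(analytic - fd)) / max(fd, 1e-12), 1e-4)
  }
})

test_that("class averages combine per-sample profiles elementwise", {
  # hand-computed linear profiles (1,3) and (3,1) average to (2,2)
  ae <- linear_encoder(matrix(c(1, 3), 2, 1))
  # per-sample linear profiles do not depend on x, so force them through
  # the matrix interface with two samples
  X <- matrix(runif(4), 2, 2, dimnames = list(c("s1", "s2"), c("x1", "x2")))
  S <- activation_gradient(ae, X)
  expect_equal(dim(S), c(2L, 2L))
  avg <- class_average_activation(ae, X)
  expect_equal(as.numeric(avg), unname(colMeans(S)))
  expect_identical(attr(avg, "scope"), "class-average")
  expect_identical(attr(avg, "n_samples"), 2L)

  # single sample: average equals the profile itself
  one <- class_average_activation(ae, X[1, , drop = FALSE])
  expect_equal(as.numeric(one),
               as.numeric(activation_gradient(ae, X[1, ])))

  # duplicating the sample set leaves the average unchanged
  dup <- class_average_activation(ae, rbind(X, X))
  expect_equal(as.numeric(dup), as.numeric(avg))

  expect_error(class_average_activation(ae, X[0, , drop = FALSE]),
               "at least one")
})

test_that("top_features returns the minimal covering prefix", {
  prof <- activation_profile(c(a = 0.5, b = 0.3, c = 0.2), "class-average", 1)
  kf <- top_features(prof, 0.75)
  expect_identical(kf$feature, c("a", "b"))
  expect_equal(kf$cum_fraction[2], 0.8)
  # minimality: dropping the last included feature falls below threshold
  expect_lt(kf$cum_fraction[1], 0.75)

  # threshold 1 returns every feature with nonzero score
  prof2 <- activation_profile(c(a = 0.5, b = 0.5, c = 0), "class-average", 1)
  expect_setequal(top_features(prof2, 1)$feature, c("a", "b"))

  # boundary ties are all included, ordered by name
  prof3 <- activation_profile(c(b = 0.4, a = 0.4, c = 0.2), "class-average", 1)
  kf3 <- top_features(prof3, 0.5)
  expect_identical(kf3$feature, c("a", "b"))

  expect_error(top_features(activation_profile(c(a = 0, b = 0),
                                               "class-average", 1), 0.75),
               "zero")
})

test_that("shared and class-average-only feature sets follow set algebra", {
  p1 <- activation_profile(c(m = 5, n = 4, q = 1), "sample-set", 2)
  p2 <- activation_profile(c(m = 5, q = 4, n = 1), "sample-set", 2)
  p3 <- activation_profile(c(m = 6, n = 3, q = 1), "sample-set", 2)
  # m in every top-75% set; n only in two of three
  expect_identical(shared_key_features(list(p1, p2, p3), 0.75), "m")
  expect_identical(shared_key_features(list(p1, p1), 0.75),
                   top_features(p1, 0.75)$feature)
  d1 <- activation_profile(c(m = 1, n = 0, q = 0), "sample-set", 1)
  d2 <- activation_profile(c(m = 0, n = 1, q = 0), "sample-set", 1)
  expect_length(shared_key_features(list(d1, d2), 0.75), 0)

  # class-average-only: in every class top set, in no sample top set
  cls1 <- activation_profile(c(m = 5, z = 4, q = 1), "class-average", 10)
  cls2 <- activation_profile(c(m = 4, z = 5, q = 1), "class-average", 10)
  only <- class_average_only_features(list(p1, p2), list(cls1, cls2), 0.75)
  expect_identical(only, "z")
  expect_length(class_average_only_features(list(cls1), list(cls1), 0.75), 0)
  expect_error(class_average_only_features(list(p1), list(), 0.75), "class")
})

test_that("trend annotation requires strict agreement across node samples", {
  S <- rbind(s1 = c(f = 2.0, g = 0.5, h = 1.0),
             s2 = c(f = 1.5, g = 0.8, h = 1.0))
  cls <- c("a+", "b+")
  profs <- list(
    "a+" = activation_profile(c(f = 1.0, g = 1.0, h = 1.0), "class-average", 5),
    "b+" = activation_profile(c(f = 1.0, g = 1.0, h = 1.0), "class-average", 5))
  tr <- annotate_trends(S, cls, profs)
  expect_identical(unname(tr), c("up", "down", "none"))

  # mixed above/below gives none
  S2 <- rbind(s1 = c(f = 2), s2 = c(f = 0.5))
  colnames(S2) <- "f"
  tr2 <- annotate_trends(S2, cls, profs, features = "f")
  expect_identical(unname(tr2), "none")
  expect_error(annotate_trends(S, c("a+", "zz"), profs), "zz")
})

test_that("per-class expression summaries use stated quantile conventions", {
  ids <- paste0("S", 1:10)
  m <- toy_matrix(cbind(f1 = c(1:5, rep(3, 5)), f2 = rep(7, 10)),
                  ids = ids, feats = c("f1", "f2"))
  ont <- toy_ontology(ids, rep(c("a", "b"), each = 5), rep(1, 10))
  out <- expression_summary(m, ont, "f1")
  a <- out[out$class == "a+", ]
  expect_equal(c(a$median, a$q1, a$q3), c(3, 2, 4))
  b <- out[out$class == "b+", ]
  expect_equal(c(b$median, b$q1, b$q3, b$whisker_lo, b$whisker_hi),
               c(3, 3, 3, 3, 3))
  # a constant feature summarizes identically across classes
  out2 <- expression_summary(m, ont, "f2")
  expect_equal(out2$median, c(7, 7))
  expect_error(expression_summary(m, ont, "nope"), "unknown feature")
})

test_that("attribution concentrates on dominant informative features", {
  # two classes whose only structured signal is their marker block; the
  # background is near-constant. The encoder's attention must then rank
  # the planted informative features above every background feature.
  set.seed(3)
  n_per <- 30; d <- 40
  cls <- rep(c("A", "B"), each = n_per)
  X <- matrix(rnorm(2 * n_per * d, 0.5, 0.01), 2 * n_per, d)
  mkA <- 1:4; mkB <- 5:8
  X[cls == "A", mkA] <- X[cls == "A", mkA] + 0.4
  X[cls == "B", mkB] <- X[cls == "B", mkB] + 0.4
  dimnames(X) <- list(paste0("s", seq_len(nrow(X))), paste0("f", seq_len(d)))
  set.seed(3)
  ae <- build_autoencoder(d, 4, 3)
  trained <- pretrain_autoencoder(ae, X, epochs = 400, batch_size = 16,
                                  lr = 2e-3)$ae
  n_planted <- length(mkA) + length(mkB)
  for (cl in c("A", "B")) {
    prof <- class_average_activation(trained, X[cls == cl, ])
    ranks <- rank(-as.numeric(prof))
    mk <- if (cl == "A") mkA else mkB
    expect_gte(mean(ranks[mk] <= n_planted), 0.8)
  }
})

test_that("class-average attribution recovers planted markers", {
  r <- fit_fixture_model(seed = 31)
  truth <- r$fx$truth
  ont <- r$pp$ontology
  X <- r$pp$expression
  hit <- vapply(names(truth$marker_map), function(cl) {
    ids <- intersect(ont$sample_id[ont$class == cl], r$pp$split$train_ids)
    prof <- class_average_activation(r$model, X[ids, ])
    mean(truth$marker_map[[cl]] %in% top_features(prof, 0.75)$feature)
  }, 0)
  expect_true(all(hit >= 0.8))
})
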