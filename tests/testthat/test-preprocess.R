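test_that("read-depth filter keeps the boundary and drops shallow samples", {
  m <- toy_matrix(cbind(c(2e6, 9e5, 1e6, 0, 3e6), 0))
  out <- filter_low_depth(m, 1e6)
  expect_identical(sample_ids(out), c("S1", "S3", "S5"))
  expect_identical(attr(out, "removed_ids"), c("S2", "S4"))

  # every row exactly at the threshold: nothing removed (inclusive bound)
  at <- toy_matrix(matrix(5e5, 3, 2))
  expect_identical(sample_ids(filter_low_depth(at, 1e6)), sample_ids(at))

  expect_error(filter_low_depth(toy_matrix(matrix(1, 2, 2)), 1e6),
               "all samples removed")
  expect_error(filter_low_depth(normalize_total_count(at), 1e6), "raw counts")
})

test_that("total-count normalization is exact and scale-invariant", {
  m <- toy_matrix(rbind(c(1, 1, 1, 1), c(10, 30, 60, 0)))
  norm <- normalize_total_count(m, scale = 1e6)
  expect_equal(unname(as.matrix(norm)[1, ]), rep(250000, 4))
  norm100 <- normalize_total_count(m, scale = 100)
  expect_equal(unname(as.matrix(norm100)[2, ]), c(10, 30, 60, 0))
  # multiplying a raw row by a constant leaves its normalized row unchanged
  m2 <- toy_matrix(rbind(c(1, 1, 1, 1), 7 * c(10, 30, 60, 0)))
  expect_equal(as.matrix(normalize_total_count(m2, 100)),
               as.matrix(norm100))
  zero <- toy_matrix(rbind(c(1, 1), c(0, 0)))
  expect_error(normalize_total_count(zero), "S2")
})

test_that("IQR outlier removal applies type-7 quartile fences", {
  # engineered summaries {1,2,3,4,100} via a first-feature summary statistic
  vals <- cbind(c(1, 2, 3, 4, 100), 200 - c(1, 2, 3, 4, 100))
  m <- toy_matrix(vals, normalized = TRUE)
  res <- remove_outliers_iqr(m, k = 1.5, summary_fun = function(v) v[1])
  expect_identical(res$removed_ids, "S5")
  # Q1 = 2, Q3 = 4 by linear interpolation -> fences [-1, 7]
  expect_equal(unname(res$fences), c(-1, 7))

  # idempotent on the retained set
  res2 <- remove_outliers_iqr(res$expression, k = 1.5,
                              summary_fun = function(v) v[1])
  expect_length(res2$removed_ids, 0)

  # identical summaries: IQR = 0, everything sits on the fence, none removed
  flat <- toy_matrix(matrix(50, 5, 2), normalized = TRUE)
  expect_length(remove_outliers_iqr(flat)$removed_ids, 0)

  expect_error(remove_outliers_iqr(toy_matrix(matrix(1, 3, 2),
                                              normalized = TRUE)),
               ">= 4 samples")
})

test_that("presence-fraction feature filter drops rare features only", {
  vals <- cbind(a = c(5, 0, 0, 0), b = c(1, 2, 3, 4), c = c(0, 0, 0, 0))
  vals <- vals / rowSums(vals) * 100
  m <- toy_matrix(vals, feats = c("a", "b", "c"), normalized = TRUE)
  out <- filter_features(m, 0.5)
  expect_identical(feature_names(out), "b")
  expect_identical(attr(out, "removed_features"), c("a", "c"))
  # zero threshold is the identity
  expect_identical(feature_names(filter_features(m, 0)), c("a", "b", "c"))
  # an all-zero feature is removed at any positive threshold
  expect_false("c" %in% feature_names(filter_features(m, 1e-9)))
})

test_that("small combined classes are removed from matrix and ontology", {
  sizes <- c(12, 9, 10)
  ids <- paste0("S", seq_len(sum(sizes)))
  ont <- toy_ontology(ids, rep(c("a", "b", "c"), sizes),
                      rep(c(1, 0, 1), sizes))
  m <- toy_matrix(matrix(1, sum(sizes), 3), ids = ids)
  out <- drop_small_classes(m, ont, min_n = 10)
  expect_equal(nrow(out$expression), 22)
  expect_false("b-" %in% out$ontology$class)
  expect_length(out$removed_ids, 9)
  # min_n = 1 is the identity
  expect_equal(nrow(drop_small_classes(m, ont, 1)$expression), sum(sizes))
})

test_that("stratified split respects fractions, determinism and coverage", {
  ids <- paste0("S", 1:10)
  ont <- toy_ontology(ids, rep("a", 10), rep(1, 10))
  sp <- stratified_split(ont, test_frac = 0.4, val_frac = 0, seed = 3)
  expect_length(sp$test_ids, 4)
  expect_length(sp$train_ids, 6)
  expect_length(sp$val_ids, 0)

  # same seed twice: identical; different seed: same counts
  sp2 <- stratified_split(ont, 0.4, 0, seed = 3)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(ont, 0.4, 0, seed = 4)
  expect_length(sp3$test_ids, 4)

  # partition property over a multi-class cohort with validation
  fx <- generate_minimal_fixture()
  sp4 <- stratified_split(fx$ontology, 0.4, 0.2, seed = 1)
  all_ids <- c(sp4$train_ids, sp4$val_ids, sp4$test_ids)
  expect_setequal(all_ids, fx$ontology$sample_id)
  expect_identical(anyDuplicated(all_ids), 0L)
  # per-class test counts within rounding of test_frac * n
  for (cl in unique(fx$ontology$class)) {
    cl_ids <- fx$ontology$sample_id[fx$ontology$class == cl]
    n_test <- sum(sp4$test_ids %in% cl_ids)
    expect_lt(abs(n_test - 0.4 * length(cl_ids)), 1)
    expect_gt(sum(sp4$train_ids %in% cl_ids), 0)
  }
  ont1 <- toy_ontology(c("x", "y", "z"), c("a", "a", "b"), c(1, 1, 1))
  expect_error(stratified_split(ont1, 0.4, 0.2, 1), "drop_small_classes")
})

test_that("the full pipeline removes planted QC failures and reports reasons", {
  coh <- generate_cohort(synth_config(samples_per_class = 20, seed = 5))
  pp <- preprocess_pipeline(coh$expression, coh$ontology, seed = 5)
  low <- pp$removed$sample_id[pp$removed$reason == "low_depth"]
  out <- pp$removed$sample_id[pp$removed$reason == "iqr_outlier"]
  expect_setequal(low, coh$truth$planted_lowdepth_ids)
  expect_setequal(out, coh$truth$planted_outlier_ids)
  # normalized output: row sums constant within 1e-6 relative tolerance
  rs <- rowSums(as.matrix(pp$expression))
  expect_lt(max(abs(rs - 1e6)) / 1e6, 1e-6)
  # re-running the pipeline on its own output removes nothing further
  res2 <- remove_outliers_iqr(pp$expression)
  expect_length(res2$removed_ids, 0)
})
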