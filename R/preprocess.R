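#' Remove low-depth samples
#'
#' Drops samples whose total read count falls below `min_reads`. The
#' threshold is inclusive: a sample with exactly `min_reads` reads is kept.
#' Intended for raw count matrices before normalization.
#'
#' @param x an `expr_matrix` of raw counts.
#' @param min_reads minimum total reads per sample (default one million).
#' @return An `expr_matrix` with the failing samples removed, with attribute
#'   `"removed_ids"` listing them. Sample order is preserved.
#' @export
filter_low_depth <- function(x, min_reads = 1e6) {
  if (is_normalized(x)) stop_input("filter_low_depth() expects raw counts")
  if (min_reads <= 0) stop_input("`min_reads` must be > 0")
  keep <- rowSums(x$values) >= min_reads
  if (!any(keep)) stop_input("all samples removed: every total < ", min_reads)
  out <- x[keep, ]
  attr(out, "removed_ids") <- sample_ids(x)[!keep]
  out
}

#' Total-count normalization
#'
#' Rescales every sample to a common total: each row is divided by its sum
#' and multiplied by `scale`. The default `scale = 1e6` yields
#' reads-per-million.
#'
#' @param x an `expr_matrix` (raw).
#' @param scale target row total (default `1e6`).
#' @return A normalized `expr_matrix` whose rows each sum to `scale`.
#' @export
normalize_total_count <- function(x, scale = 1e6) {
  rs <- rowSums(x$values)
  if (any(rs == 0)) {
    stop_input("zero-total sample(s): ",
               paste(sample_ids(x)[rs == 0], collapse = ", "))
  }
  expression_matrix(x$values / rs * scale, normalized = TRUE)
}

#' IQR-based outlier sample removal
#'
#' Summarizes every sample with a single scalar (by default the mean of
#' log2(normalized value + 1) across features, a standard per-sample quality
#' summary), computes the first and third quartiles of the summaries over the
#' cohort with linear-interpolation (type-7) quantiles, and removes samples
#' outside `[Q1 - k*IQR, Q3 + k*IQR]`.
#'
#' @param x a normalized `expr_matrix`.
#' @param k fence multiplier (default 1.5).
#' @param summary_fun function mapping one sample's expression vector to a
#'   scalar; default `function(v) mean(log2(v + 1))`.
#' @return A list with elements `expression` (retained samples),
#'   `removed_ids`, `summaries` (named per-sample scalars) and `fences`
#'   (`c(lower, upper)`).
#' @export
remove_outliers_iqr <- function(x, k = 1.5, summary_fun = NULL) {
  if (!is_normalized(x)) stop_input("remove_outliers_iqr() expects a normalized matrix")
  if (k <= 0) stop_input("`k` must be > 0")
  if (nrow(x$values) < 4) stop_input("need >= 4 samples for quartile fences")
  summary_fun <- summary_fun %||% function(v) mean(log2(v + 1))
  s <- apply(x$values, 1, summary_fun)
  q <- stats::quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  keep <- s >= fences[1] & s <= fences[2]
  list(expression = x[keep, ],
       removed_ids = sample_ids(x)[!keep],
       summaries = s,
       fences = fences)
}

#' Presence-fraction feature filter
#'
#' Keeps features expressed (value > 0) in at least `min_fraction_expressed`
#' of samples. Feature order is preserved. With the default 0.1 this removes
#' miRNAs detected in fewer than 10% of samples.
#'
#' @param x a normalized `expr_matrix`.
#' @param min_fraction_expressed required fraction of samples with value > 0.
#' @return An `expr_matrix` with the retained features; attribute
#'   `"removed_features"` lists the dropped names. Note the normalization
#'   flag is cleared, since row totals change when columns are dropped.
#' @export
filter_features <- function(x, min_fraction_expressed = 0.1) {
  if (min_fraction_expressed < 0 || min_fraction_expressed > 1) {
    stop_input("`min_fraction_expressed` must be in [0, 1]")
  }
  frac <- colMeans(x$values > 0)
  keep <- frac >= min_fraction_expressed
  if (min_fraction_expressed == 0) keep[] <- TRUE
  if (!any(keep)) stop_input("all features removed")
  out <- x[, keep]
  attr(out, "removed_features") <- feature_names(x)[!keep]
  out
}

#' Drop combined classes with too few samples
#'
#' Removes every sample whose combined (tissue, neoplasticity) class has
#' fewer than `min_n` members, from both the matrix and the ontology.
#'
#' @param x an `expr_matrix`.
#' @param ontology a `sample_ontology` covering all samples in `x`.
#' @param min_n minimum class size (default 10).
#' @return A list with `expression`, `ontology` and `removed_ids`.
#' @export
drop_small_classes <- function(x, ontology, min_n = 10) {
  if (min_n < 1) stop_input("`min_n` must be >= 1")
  ont <- match_ontology(ontology, sample_ids(x))
  sizes <- table(ont$class)
  keep_class <- names(sizes)[sizes >= min_n]
  keep <- ont$class %in% keep_class
  if (!any(keep)) warning("all classes below min_n; returning empty cohort")
  out_ont <- ont[keep, , drop = FALSE]
  class(out_ont) <- c("sample_ontology", "data.frame")
  list(expression = x[keep, ],
       ontology = out_ont,
       removed_ids = ont$sample_id[!keep])
}

# Align an ontology to a set of sample ids (order of ids, error if missing).
match_ontology <- function(ontology, ids) {
  m <- match(ids, ontology$sample_id)
  if (anyNA(m)) {
    stop_input("samples missing from ontology: ",
               paste(utils::head(ids[is.na(m)], 5), collapse = ", "))
  }
  out <- ontology[m, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sample_ontology", "data.frame")
  out
}

#' Stratified train/validation/test split
#'
#' Splits samples by combined class: within every class, `round(test_frac *
#' n)` samples (clamped to `[1, n - 1]`) go to the test set, then
#' `round(val_frac * m)` of the remaining `m` training samples (clamped to
#' keep at least one training sample) are set aside for validation. With the
#' defaults this is the 40-60 test/train division with a further 20% of
#' training data reserved for validation. Deterministic given `seed`.
#'
#' @param ontology a `sample_ontology`.
#' @param test_frac fraction per class assigned to test (default 0.4).
#' @param val_frac fraction of the per-class training remainder assigned to
#'   validation (default 0.2).
#' @param seed integer seed.
#' @return An object of class `split_assignment`: list with `train_ids`,
#'   `val_ids`, `test_ids`.
#' @export
stratified_split <- function(ontology, test_frac = 0.4, val_frac = 0.2,
                             seed = 1L) {
  if (test_frac <= 0 || test_frac >= 1) stop_input("`test_frac` must be in (0, 1)")
  if (val_frac < 0 || val_frac >= 1) stop_input("`val_frac` must be in [0, 1)")
  sizes <- table(ontology$class)
  if (any(sizes < 2)) {
    stop_input("class(es) with a single sample: ",
               paste(names(sizes)[sizes < 2], collapse = ", "),
               "; run drop_small_classes() first")
  }
  set.seed(as.integer(seed))
  train <- character(0); val <- character(0); test <- character(0)
  for (cl in sort(names(sizes))) {
    ids <- ontology$sample_id[ontology$class == cl]
    n <- length(ids)
    n_test <- min(max(round(test_frac * n), 1L), n - 1L)
    ids <- sample(ids)
    test_i <- ids[seq_len(n_test)]
    rest <- ids[-seq_len(n_test)]
    n_val <- min(round(val_frac * length(rest)), length(rest) - 1L)
    n_val <- max(n_val, 0L)
    val_i <- if (n_val > 0) rest[seq_len(n_val)] else character(0)
    train_i <- setdiff(rest, val_i)
    train <- c(train, train_i); val <- c(val, val_i); test <- c(test, test_i)
  }
  structure(list(train_ids = train, val_ids = val, test_ids = test),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split_assignment: %d train / %d validation / %d test\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids)))
  invisible(x)
}

#' Full preprocessing pipeline
#'
#' Runs the fixed quality-control order: read-depth filter, total-count
#' normalization, IQR outlier removal, presence-fraction feature filter,
#' small-class removal, and the stratified split. A removed-sample report
#' records every dropped sample and the stage that dropped it.
#'
#' @param x raw-count `expr_matrix`.
#' @param ontology a `sample_ontology`.
#' @param min_reads,scale,iqr_k,summary_fun,min_fraction_expressed,min_class_size
#'   stage parameters; see the individual stage functions.
#' @param test_frac,val_frac,seed split parameters; see [stratified_split()].
#' @return A list of class `dnm_preprocess` with elements `expression`
#'   (normalized, filtered), `ontology`, `split`, `removed` (data frame
#'   `sample_id`, `reason`), `removed_features` and `params`.
#' @export
preprocess_pipeline <- function(x, ontology,
                                min_reads = 1e6, scale = 1e6,
                                iqr_k = 1.5, summary_fun = NULL,
                                min_fraction_expressed = 0.1,
                                min_class_size = 10,
                                test_frac = 0.4, val_frac = 0.2, seed = 1L) {
  removed <- data.frame(sample_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  note <- function(ids, why) {
    if (length(ids)) {
      rbind(removed, data.frame(sample_id = ids, reason = why,
                                stringsAsFactors = FALSE))
    } else removed
  }

  depth <- filter_low_depth(x, min_reads)
  removed <- note(attr(depth, "removed_ids"), "low_depth")

  norm <- normalize_total_count(depth, scale)

  iqr <- remove_outliers_iqr(norm, k = iqr_k, summary_fun = summary_fun)
  removed <- note(iqr$removed_ids, "iqr_outlier")

  feats <- filter_features(iqr$expression, min_fraction_expressed)
  # Renormalize after dropping features so rows again share a common total.
  feats <- normalize_total_count(feats, scale)

  cls <- drop_small_classes(feats, ontology, min_class_size)
  removed <- note(cls$removed_ids, "small_class")

  split <- stratified_split(cls$ontology, test_frac, val_frac, seed)

  structure(list(expression = cls$expression,
                 ontology = cls$ontology,
                 split = split,
                 removed = removed,
                 removed_features = attr(feats, "removed_features"),
                 params = list(min_reads = min_reads, scale = scale,
                               iqr_k = iqr_k,
                               min_fraction_expressed = min_fraction_expressed,
                               min_class_size = min_class_size,
                               test_frac = test_frac, val_frac = val_frac,
                               seed = seed)),
            class = "dnm_preprocess")
}

#' @export
print.dnm_preprocess <- function(x, ...) {
  cat(sprintf("dnm_preprocess: %d samples x %d features retained\n",
              nrow(x$expression), ncol(x$expression)))
  if (nrow(x$removed)) {
    tab <- table(x$removed$reason)
    cat("  removed:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  print(x$split)
  invisible(x)
}
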