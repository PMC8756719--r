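#' Majority-vote node labelling
#'
#' Assigns each lattice node the combined class holding a strict majority
#' among the training samples mapped there. Nodes with no samples, or with
#' a tie for the most frequent class, stay unlabelled. Per-node class
#' counts are retained for auditing.
#'
#' @param assign a `bmu_assignment` of training samples (from
#'   [map_samples()]).
#' @param ontology a `sample_ontology` covering the assigned samples.
#' @param som_dim `c(H, W)`; defaults to the assignment's `"som_dim"`
#'   attribute.
#' @return An object of class `node_labels`: list with `labels` (H x W
#'   character matrix, `NA` = unlabelled), `counts` (nodes x classes count
#'   matrix, row-major node order), `classes` (class / tissue / status
#'   lookup), `H`, `W`.
#' @export
label_nodes <- function(assign, ontology, som_dim = attr(assign, "som_dim")) {
  if (is.null(som_dim)) stop_input("`som_dim` not available; pass it explicitly")
  H <- som_dim[1]; W <- som_dim[2]
  ont <- match_ontology(ontology, assign$sample_id)
  node <- assign$row * W + assign$col + 1L
  classes <- sort(unique(ont$class))
  counts <- matrix(0L, H * W, length(classes),
                   dimnames = list(NULL, classes))
  tab <- table(factor(node, levels = seq_len(H * W)),
               factor(ont$class, levels = classes))
  counts[] <- as.integer(tab)
  labels <- rep(NA_character_, H * W)
  for (i in which(rowSums(counts) > 0)) {
    mx <- max(counts[i, ])
    winners <- colnames(counts)[counts[i, ] == mx]
    if (length(winners) == 1) labels[i] <- winners
  }
  proj <- class_projection(classes)
  structure(list(labels = matrix(labels, H, W, byrow = TRUE),
                 counts = counts,
                 classes = data.frame(class = classes,
                                      tissue = proj$tissue,
                                      neoplastic = proj$neoplastic,
                                      stringsAsFactors = FALSE),
                 H = H, W = W),
            class = "node_labels")
}

#' @export
print.node_labels <- function(x, ...) {
  n_lab <- sum(!is.na(x$labels))
  cat(sprintf("node_labels: %d x %d lattice, %d labelled / %d nodes, %d classes\n",
              x$H, x$W, n_lab, x$H * x$W, nrow(x$classes)))
  invisible(x)
}

# Predicted combined class per sample: its node's label (NA if unlabelled).
predict_node_label <- function(assign, labels) {
  idx <- cbind(assign$row + 1L, assign$col + 1L)
  labels$labels[idx]
}

#' Classify samples by their node labels
#'
#' Each sample's predicted combined class is the label of its winning
#' node. By default, samples landing on unlabelled nodes count as
#' misclassified for every metric (`unlabeled = "misclassify"`);
#' `unlabeled = "exclude"` drops them instead. Tissue-only and
#' neoplasticity-only accuracies are computed by projecting the combined
#' node label onto each axis, so the combined accuracy can never exceed
#' either projection. Sensitivity and specificity take neoplastic as the
#' positive class.
#'
#' @param assign a `bmu_assignment` of the samples to score.
#' @param labels a `node_labels` from [label_nodes()].
#' @param ontology a `sample_ontology` with the true labels.
#' @param unlabeled how to treat samples on unlabelled nodes.
#' @return An object of class `dnm_eval`: list with `accuracy` (named
#'   vector: combined, tissue, neoplastic), `sensitivity`, `specificity`,
#'   `confusion` (actual x predicted counts, including an `UNLABELED`
#'   column), `n_scored`, `n_unlabeled` and `unlabeled_mode`.
#' @export
classify_samples <- function(assign, labels, ontology,
                             unlabeled = c("misclassify", "exclude")) {
  unlabeled <- match.arg(unlabeled)
  ont <- match_ontology(ontology, assign$sample_id)
  pred <- predict_node_label(assign, labels)
  on_unlabeled <- is.na(pred)
  keep <- if (unlabeled == "exclude") !on_unlabeled else rep(TRUE, length(pred))
  truth <- ont[keep, , drop = FALSE]
  pred <- pred[keep]

  pred_proj <- class_projection(ifelse(is.na(pred), "", pred))
  ok_combined <- !is.na(pred) & pred == truth$class
  ok_tissue <- !is.na(pred) & pred_proj$tissue == truth$tissue
  ok_neo <- !is.na(pred) & pred_proj$neoplastic == truth$neoplastic

  pos <- truth$neoplastic
  pred_pos <- !is.na(pred) & pred_proj$neoplastic
  pred_neg <- !is.na(pred) & !pred_proj$neoplastic
  sens <- if (any(pos)) mean(pred_pos[pos]) else NA_real_
  spec <- if (any(!pos)) mean(pred_neg[!pos]) else NA_real_

  all_classes <- sort(unique(c(truth$class, labels$classes$class)))
  conf <- table(factor(truth$class, levels = all_classes),
                factor(ifelse(is.na(pred), "UNLABELED", pred),
                       levels = c(all_classes, "UNLABELED")))
  conf <- unclass(conf)
  names(dimnames(conf)) <- c("actual", "predicted")

  structure(list(accuracy = c(combined = mean(ok_combined),
                              tissue = mean(ok_tissue),
                              neoplastic = mean(ok_neo)),
                 sensitivity = sens, specificity = spec,
                 confusion = conf,
                 n_scored = nrow(truth), n_unlabeled = sum(on_unlabeled),
                 unlabeled_mode = unlabeled),
            class = "dnm_eval")
}

#' @export
print.dnm_eval <- function(x, ...) {
  cat("Deep Neural Map evaluation\n")
  cat(sprintf("  combined accuracy:     %.4f\n", x$accuracy["combined"]))
  cat(sprintf("  tissue accuracy:       %.4f\n", x$accuracy["tissue"]))
  cat(sprintf("  neoplasticity accuracy: %.4f\n", x$accuracy["neoplastic"]))
  cat(sprintf("  sensitivity %.4f / specificity %.4f (neoplastic positive)\n",
              x$sensitivity, x$specificity))
  cat(sprintf("  %d samples scored; %d on unlabelled nodes (%s)\n",
              x$n_scored, x$n_unlabeled, x$unlabeled_mode))
  invisible(x)
}

#' Confusion matrix of combined-class predictions
#'
#' Rows are the actual combined classes; columns the predicted node
#' labels plus a dedicated `UNLABELED` column, so every row sums to that
#' class's sample count.
#'
#' @inheritParams classify_samples
#' @return An actual x predicted count matrix.
#' @export
confusion_matrix <- function(assign, labels, ontology) {
  classify_samples(assign, labels, ontology)$confusion
}

#' Per-node sample density
#'
#' @param assign a `bmu_assignment`.
#' @param som_dim `c(H, W)`; defaults to the assignment's attribute.
#' @param subset optional vector of sample identifiers to count.
#' @return An H x W integer matrix of counts; the total equals the number
#'   of (subsetted) samples.
#' @export
density_map <- function(assign, som_dim = attr(assign, "som_dim"),
                        subset = NULL) {
  if (is.null(som_dim)) stop_input("`som_dim` not available; pass it explicitly")
  a <- if (is.null(subset)) assign else assign[assign$sample_id %in% subset, ]
  H <- som_dim[1]; W <- som_dim[2]
  out <- matrix(0L, H, W)
  if (nrow(a)) {
    tab <- table(factor(a$row * W + a$col + 1L, levels = seq_len(H * W)))
    out <- matrix(as.integer(tab), H, W, byrow = TRUE)
  }
  out
}

#' Find multi-class lattice nodes
#'
#' Identifies nodes where samples from `min_classes` or more distinct
#' combined classes are mapped, optionally restricted to neoplastic or
#' non-neoplastic samples. These are the nodes worth inspecting with
#' sample-specific activation gradients.
#'
#' @param assign a `bmu_assignment`.
#' @param ontology a `sample_ontology`.
#' @param min_classes minimum number of distinct combined classes
#'   (default 3).
#' @param status restrict to `"neoplastic"` or `"non-neoplastic"` samples,
#'   or use `"any"` (default).
#' @return A data frame of class `multiclass_nodes` with columns `row`,
#'   `col`, `n_classes`, `n_samples` and `classes` (a `"class(n)"`
#'   summary string); attribute `"rosters"` holds, per node, the list of
#'   sample identifiers by class.
#' @export
find_multiclass_nodes <- function(assign, ontology, min_classes = 3,
                                  status = c("any", "neoplastic",
                                             "non-neoplastic")) {
  status <- match.arg(status)
  if (min_classes < 2) stop_input("`min_classes` must be >= 2")
  ont <- match_ontology(ontology, assign$sample_id)
  keep <- switch(status,
                 any = rep(TRUE, nrow(ont)),
                 neoplastic = ont$neoplastic,
                 `non-neoplastic` = !ont$neoplastic)
  a <- assign[keep, , drop = FALSE]
  ont <- ont[keep, , drop = FALSE]
  key <- paste(a$row, a$col, sep = ",")
  rosters <- list()
  rows <- list()
  for (k in unique(key)) {
    sel <- key == k
    cls <- ont$class[sel]
    n_cls <- length(unique(cls))
    if (n_cls >= min_classes) {
      by_class <- split(a$sample_id[sel], cls)
      counts <- vapply(by_class, length, 0L)
      rc <- as.integer(strsplit(k, ",")[[1]])
      rows[[length(rows) + 1]] <- data.frame(
        row = rc[1], col = rc[2], n_classes = n_cls, n_samples = sum(sel),
        classes = paste(sprintf("%s(%d)", names(counts), counts),
                        collapse = ", "),
        stringsAsFactors = FALSE)
      rosters[[k]] <- by_class
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(row = integer(0), col = integer(0), n_classes = integer(0),
               n_samples = integer(0), classes = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rosters") <- rosters
  class(out) <- c("multiclass_nodes", "data.frame")
  out
}

#' Serialize an evaluation report to JSON / TSV
#'
#' @param eval a `dnm_eval`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  out <- list(accuracy = as.list(eval$accuracy),
              sensitivity = eval$sensitivity,
              specificity = eval$specificity,
              n_scored = eval$n_scored,
              n_unlabeled = eval$n_unlabeled,
              unlabeled_mode = eval$unlabeled_mode,
              confusion = list(classes = rownames(eval$confusion),
                               predicted = colnames(eval$confusion),
                               counts = unname(apply(eval$confusion, 1,
                                                     as.integer,
                                                     simplify = FALSE))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
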