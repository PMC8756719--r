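#' Expression matrix container
#'
#' A light container for a samples x features miRNA expression matrix. Rows
#' are samples, columns are miRNA features. Values must be finite and
#' non-negative; sample identifiers and feature names must be unique. The
#' `normalized` flag records whether rows have been rescaled to a common
#' total (see [normalize_total_count()]); when set, every row must sum to the
#' same constant within 1e-6 relative tolerance.
#'
#' @param values numeric matrix, samples in rows, features in columns. Row
#'   names are sample identifiers, column names are miRNA names.
#' @param normalized logical; whether rows are on a common-total scale.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `normalized`.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("miR-", 1:4)))
#' em <- expression_matrix(m)
#' dim(em)
#' @export
expression_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("`values` must be a numeric matrix (samples x features)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_input("`values` must have sample row names and feature column names")
  }
  if (anyDuplicated(rownames(values))) stop_input("duplicated sample identifiers")
  if (anyDuplicated(colnames(values))) stop_input("duplicated feature names")
  if (!all(is.finite(values))) stop_input("expression values must be finite")
  if (any(values < 0)) stop_input("expression values must be >= 0")
  if (isTRUE(normalized) && nrow(values) > 1) {
    rs <- rowSums(values)
    if (max(abs(rs - rs[1])) > 1e-6 * max(rs[1], .Machine$double.eps)) {
      stop_input("normalized = TRUE but row sums are not constant")
    }
  }
  structure(list(values = values, normalized = isTRUE(normalized)),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' Sample identifiers and feature names
#' @param x an `expr_matrix`.
#' @return Character vector of sample identifiers or feature names.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
feature_names <- function(x) colnames(x$values)

#' Is the matrix on a common-total scale?
#' @param x an `expr_matrix`.
#' @return Logical flag.
#' @export
is_normalized <- function(x) isTRUE(x$normalized)

#' Subset an expression matrix
#'
#' Subsetting keeps the container class and the normalization flag for row
#' (sample) subsets; selecting a strict subset of features clears the flag,
#' since row sums are no longer constant.
#'
#' @param x an `expr_matrix`.
#' @param i,j sample / feature indices (numeric, logical, or names).
#' @param ... ignored.
#' @return An `expr_matrix`.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  v <- x$values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  sub <- v[i, j, drop = FALSE]
  norm <- x$normalized && ncol(sub) == ncol(v)
  expression_matrix(sub, normalized = norm)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' Per-sample ontology labels
#'
#' Builds the per-sample label table: tissue-of-origin, neoplasticity
#' status, and the derived combined class used for stratification and node
#' labelling. The combined class is written `"<tissue>+"` for neoplastic and
#' `"<tissue>-"` for non-neoplastic samples.
#'
#' @param sample_id character vector of unique sample identifiers, or a
#'   data frame with columns `sample_id`, `tissue`, `neoplastic`.
#' @param tissue character vector of tissue-of-origin labels.
#' @param neoplastic logical, 0/1, or `"neoplastic"`/`"non-neoplastic"`.
#' @return A data frame of class `sample_ontology` with columns `sample_id`,
#'   `tissue`, `neoplastic` (logical) and `class`.
#' @export
sample_ontology <- function(sample_id, tissue = NULL, neoplastic = NULL) {
  if (is.data.frame(sample_id)) {
    df <- sample_id
    need <- c("sample_id", "tissue", "neoplastic")
    if (!all(need %in% names(df))) {
      stop_input("ontology table needs columns: ", paste(need, collapse = ", "))
    }
    sample_id <- as.character(df$sample_id)
    tissue <- as.character(df$tissue)
    neoplastic <- df$neoplastic
  }
  if (anyDuplicated(sample_id)) stop_input("duplicated sample_id in ontology")
  neo <- parse_neoplastic(neoplastic)
  out <- data.frame(sample_id = as.character(sample_id),
                    tissue = as.character(tissue),
                    neoplastic = neo,
                    class = paste0(tissue, ifelse(neo, "+", "-")),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_ontology", "data.frame")
  out
}

parse_neoplastic <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop_input("numeric neoplastic status must be 0/1")
    return(x == 1)
  }
  x <- tolower(as.character(x))
  ok <- x %in% c("neoplastic", "non-neoplastic")
  if (!all(ok)) {
    stop_input("neoplastic status values must be logical, 0/1, or ",
               "'neoplastic'/'non-neoplastic'; got: ",
               paste(unique(x[!ok]), collapse = ", "))
  }
  x == "neoplastic"
}

# Split a combined class label back into its (tissue, status) projections.
class_projection <- function(class) {
  list(tissue = sub("[+-]$", "", class),
       neoplastic = grepl("\\+$", class))
}

#' Read / write expression matrices and ontology tables
#'
#' Expression files are TSV/CSV with the sample identifier in the first
#' column and one column per miRNA. Ontology files have columns
#' `sample_id`, `tissue`, `neoplastic`.
#'
#' @param path file path.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @param normalized logical flag to attach to the matrix read.
#' @return `read_expression_matrix()` returns an `expr_matrix`;
#'   `read_sample_ontology()` a `sample_ontology`.
#' @export
read_expression_matrix <- function(path, sep = "\t", normalized = FALSE) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_input("expression table needs sample_id + >=1 feature: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_input("non-numeric expression values in ", path)
  rownames(m) <- ids
  expression_matrix(m, normalized = normalized)
}

#' @rdname read_expression_matrix
#' @param x object to write (`expr_matrix` or `sample_ontology`).
#' @export
write_expression_matrix <- function(x, path, sep = "\t") {
  df <- data.frame(sample_id = sample_ids(x), as.data.frame(x$values),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression_matrix
#' @export
read_sample_ontology <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_input("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  sample_ontology(df)
}

#' @rdname read_expression_matrix
#' @export
write_sample_ontology <- function(x, path, sep = "\t") {
  utils::write.table(x[, c("sample_id", "tissue", "neoplastic")], path,
                     sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
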