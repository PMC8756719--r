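#' Activation-gradient attribution
#'
#' Scores each input miRNA by the total sensitivity of the latent layer to
#' it: `score_i = sum_j |d z_j / d x_i|`, the sum over latent units of the
#' absolute partial derivative of the latent activation with respect to
#' input `i`. Derivatives are taken analytically through the encoder in
#' the scaled input space used for training; scores are reported against
#' the original miRNA names. For a purely linear encoder with one weight
#' layer this reduces to the column-wise absolute weight sums.
#'
#' @param model a fitted `dnm`, or a bare `autoencoder` (in which case `x`
#'   must already be in the network's input space).
#' @param x one sample (vector) or several (matrix / `expr_matrix`), on
#'   the training feature axis and scale.
#' @return For a single sample, an `activation_profile` (named score
#'   vector with scope `"single-sample"`). For several samples, an
#'   n x features matrix of per-sample scores.
#' @export
activation_gradient <- function(model, x) {
  enc <- attribution_encoder(model)
  X <- attribution_input(model, x)
  S <- t(apply(X, 1, function(v) encoder_jacobian_scores(enc, v)))
  colnames(S) <- enc$feature_names
  if (!all(is.finite(S))) stop_numeric("non-finite activation gradient")
  if (nrow(S) == 1) {
    activation_profile(S[1, ], scope = "single-sample", n_samples = 1)
  } else {
    rownames(S) <- rownames(X)
    S
  }
}

# Resolve model into encoder pieces shared by the attribution functions.
attribution_encoder <- function(model) {
  if (inherits(model, "dnm")) {
    ae <- model$autoencoder
    list(params = ae$params[seq_len(ae$n_encoder)], activation = ae$activation,
         input_dim = ae$layer_sizes[1], feature_names = model$features)
  } else if (inherits(model, "autoencoder")) {
    list(params = model$params[seq_len(model$n_encoder)],
         activation = model$activation, input_dim = model$layer_sizes[1],
         feature_names = paste0("x", seq_len(model$layer_sizes[1])))
  } else {
    stop_input("`model` must be a dnm or autoencoder")
  }
}

attribution_input <- function(model, x) {
  X <- if (inherits(x, "expr_matrix")) x$values else x
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (inherits(model, "dnm")) {
    if (ncol(X) != length(model$features)) {
      stop_input(sprintf("expected %d features, got %d",
                         length(model$features), ncol(X)))
    }
    X <- scaler_apply(model$scaler, X)
  }
  X
}

# score_i = sum_j |J_ij| with J the encoder Jacobian at v: J = W1 D1 W2 D2 ...
encoder_jacobian_scores <- function(enc, v) {
  a <- matrix(v, nrow = 1)
  J <- NULL
  for (l in seq_along(enc$params)) {
    z <- a %*% enc$params[[l]]$W
    z <- z + matrix(enc$params[[l]]$b, 1)
    a <- act_fun(z, enc$activation)
    s <- as.numeric(act_grad(a, enc$activation))
    Jl <- if (is.null(J)) enc$params[[l]]$W else J %*% enc$params[[l]]$W
    J <- sweep(Jl, 2, s, `*`)
  }
  rowSums(abs(J))
}

#' Activation profile container
#'
#' A named non-negative score vector with a scope (`"single-sample"`,
#' `"sample-set"` or `"class-average"`) and the number of samples averaged.
#'
#' @param scores named numeric vector of per-feature scores.
#' @param scope profile scope.
#' @param n_samples number of samples behind the profile.
#' @return An `activation_profile`.
#' @export
activation_profile <- function(scores,
                               scope = c("single-sample", "sample-set",
                                         "class-average"),
                               n_samples = 1) {
  scope <- match.arg(scope)
  if (is.null(names(scores))) stop_input("scores must be named by feature")
  if (any(!is.finite(scores)) || any(scores < 0)) {
    stop_input("scores must be finite and >= 0")
  }
  structure(as.numeric(scores), names = names(scores), scope = scope,
            n_samples = n_samples, class = "activation_profile")
}

#' @export
print.activation_profile <- function(x, ...) {
  cat(sprintf("activation_profile (%s, n = %d): %d features, total %.4g\n",
              attr(x, "scope"), attr(x, "n_samples"), length(x), sum(x)))
  top <- sort(unclass(x), decreasing = TRUE)[seq_len(min(5, length(x)))]
  cat("  top:", paste(sprintf("%s=%.3g", names(top), top), collapse = ", "),
      "\n")
  invisible(x)
}

#' Class-average activation profile
#'
#' The element-wise mean of the per-sample activation-gradient profiles of
#' a group of samples (typically all samples of one combined class, or the
#' samples mapped to one node).
#'
#' @inheritParams activation_gradient
#' @param scope scope tag for the result (default `"class-average"`).
#' @return An `activation_profile`.
#' @export
class_average_activation <- function(model, x, scope = "class-average") {
  X <- if (inherits(x, "expr_matrix")) x$values else x
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (nrow(X) < 1) stop_input("need at least one sample")
  S <- activation_gradient(model, X)
  if (inherits(S, "activation_profile")) {
    return(activation_profile(unclass(S), scope = scope, n_samples = 1))
  }
  activation_profile(colMeans(S), scope = scope, n_samples = nrow(X))
}

#' Key features covering a cumulative attribution threshold
#'
#' Ranks features by descending score and returns the minimal prefix whose
#' cumulative share of the total reaches `threshold` (default 75%).
#' Score ties at the inclusion boundary are resolved by feature-name
#' order, and all boundary-tied features are included.
#'
#' @param profile an `activation_profile` (or named score vector).
#' @param threshold cumulative-fraction cutoff in (0, 1] (default 0.75).
#' @return A data frame of class `key_features` with columns `feature`,
#'   `score`, `cum_fraction`.
#' @export
top_features <- function(profile, threshold = 0.75) {
  if (threshold <= 0 || threshold > 1) stop_input("`threshold` must be in (0, 1]")
  s <- unclass(profile)
  total <- sum(s)
  if (total <= 0) stop_input("profile total is zero; nothing to rank")
  ord <- order(-s, names(s))
  s <- s[ord]
  cf <- cumsum(s) / total
  k <- which(cf >= threshold - 1e-12)[1]
  # include all features tied with the boundary score
  k <- max(which(s >= s[k] - 1e-12 * total))
  if (threshold == 1) k <- max(which(s > 0))
  out <- data.frame(feature = names(s)[seq_len(k)],
                    score = unname(s[seq_len(k)]),
                    cum_fraction = unname(cf[seq_len(k)]),
                    stringsAsFactors = FALSE)
  class(out) <- c("key_features", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Features highly activated in every profile
#'
#' Intersection of the key-feature sets ([top_features()]) of two or more
#' activation profiles — the miRNAs highly activated in all of them.
#'
#' @param profiles list of `activation_profile`s.
#' @param threshold cumulative cutoff passed to [top_features()].
#' @return Character vector of shared feature names.
#' @export
shared_key_features <- function(profiles, threshold = 0.75) {
  if (length(profiles) < 2) stop_input("need >= 2 profiles")
  sets <- lapply(profiles, function(p) top_features(p, threshold)$feature)
  Reduce(intersect, sets)
}

#' Features prominent in class averages but absent from sample-specific sets
#'
#' Returns the features present in the key set of every class-average
#' profile yet in none of the sample-specific key sets — signal carried by
#' the class at large but not by the particular samples under study.
#'
#' @param sample_profiles list of sample-specific `activation_profile`s.
#' @param class_profiles list of class-average `activation_profile`s.
#' @param threshold cumulative cutoff passed to [top_features()].
#' @return Character vector of feature names.
#' @export
class_average_only_features <- function(sample_profiles, class_profiles,
                                        threshold = 0.75) {
  if (length(class_profiles) < 1) stop_input("need >= 1 class profile")
  in_all_class <- Reduce(intersect,
                         lapply(class_profiles,
                                function(p) top_features(p, threshold)$feature))
  in_any_sample <- unique(unlist(
    lapply(sample_profiles, function(p) top_features(p, threshold)$feature)))
  setdiff(in_all_class, in_any_sample)
}

#' Annotate per-feature activation trends at a node
#'
#' For each feature, compares every node sample's activation score with
#' the class-average score of that sample's own class: `"up"` if all
#' sample-specific scores are strictly above their class averages,
#' `"down"` if all are strictly below, `"none"` otherwise (including
#' exact equality).
#'
#' @param sample_scores matrix of per-sample activation scores (samples x
#'   features), e.g. from [activation_gradient()] on the node's samples.
#' @param sample_classes combined-class label of each row of
#'   `sample_scores`.
#' @param class_profiles named list of class-average `activation_profile`s
#'   covering every class in `sample_classes`.
#' @param features features to annotate (default: all columns).
#' @return Named character vector with values `"up"`, `"down"`, `"none"`.
#' @export
annotate_trends <- function(sample_scores, sample_classes, class_profiles,
                            features = colnames(sample_scores)) {
  if (is.null(dim(sample_scores))) sample_scores <- matrix(
    sample_scores, nrow = 1, dimnames = list(NULL, names(sample_scores)))
  missing_cls <- setdiff(unique(sample_classes), names(class_profiles))
  if (length(missing_cls)) {
    stop_input("no class-average profile for: ",
               paste(missing_cls, collapse = ", "))
  }
  ref <- do.call(rbind, lapply(sample_classes, function(cl) {
    unclass(class_profiles[[cl]])[features]
  }))
  obs <- sample_scores[, features, drop = FALSE]
  up <- apply(obs > ref, 2, all)
  down <- apply(obs < ref, 2, all)
  out <- ifelse(up, "up", ifelse(down, "down", "none"))
  names(out) <- features
  out
}

#' Report on multi-class nodes with activation-gradient context
#'
#' For every node holding samples from `min_classes` or more combined
#' classes, computes sample-specific activation profiles per class at the
#' node, their shared key features with up/down trend annotation against
#' the class-average activations, and the features prominent only in the
#' class averages.
#'
#' @param model a fitted `dnm`.
#' @param x `expr_matrix` or matrix holding (at least) the samples in
#'   `assign`.
#' @param ontology a `sample_ontology`.
#' @param assign a `bmu_assignment`; defaults to the model's training
#'   assignment.
#' @param min_classes minimum distinct classes per node (default 3).
#' @param status sample-status filter passed to
#'   [find_multiclass_nodes()] (default `"any"`).
#' @param threshold key-feature cumulative cutoff (default 0.75).
#' @return A data frame of class `multiclass_report` with one row per
#'   node: `row`, `col`, `classes`, `shared_features` (with trend arrows),
#'   `class_average_only`.
#' @export
multiclass_node_report <- function(model, x, ontology,
                                   assign = model$train_assignment,
                                   min_classes = 3, status = "any",
                                   threshold = 0.75) {
  X <- if (inherits(x, "expr_matrix")) x$values else x
  nodes <- find_multiclass_nodes(assign, ontology, min_classes, status)
  rosters <- attr(nodes, "rosters")
  ont <- match_ontology(ontology, rownames(X))

  # class-average profiles over all samples of each class in the cohort
  all_classes <- unique(unlist(lapply(rosters, names)))
  class_profiles <- lapply(all_classes, function(cl) {
    ids <- ont$sample_id[ont$class == cl]
    class_average_activation(model, X[ids, , drop = FALSE])
  })
  names(class_profiles) <- all_classes

  arrow <- c(up = " ↑", down = " ↓", none = "")
  rows <- lapply(seq_len(nrow(nodes)), function(i) {
    key <- paste(nodes$row[i], nodes$col[i], sep = ",")
    roster <- rosters[[key]]
    node_ids <- unlist(roster, use.names = FALSE)
    # sample-specific profile per class at this node
    sample_profiles <- lapply(roster, function(ids) {
      class_average_activation(model, X[ids, , drop = FALSE],
                               scope = "sample-set")
    })
    shared <- shared_key_features(sample_profiles, threshold)
    scores <- activation_gradient(model, X[node_ids, , drop = FALSE])
    if (inherits(scores, "activation_profile")) {
      scores <- matrix(unclass(scores), nrow = 1,
                       dimnames = list(node_ids, names(scores)))
    }
    cls_of <- ont$class[match(node_ids, ont$sample_id)]
    trends <- if (length(shared)) {
      annotate_trends(scores, cls_of, class_profiles, shared)
    } else character(0)
    only_avg <- class_average_only_features(
      sample_profiles, class_profiles[names(roster)], threshold)
    data.frame(row = nodes$row[i], col = nodes$col[i],
               classes = nodes$classes[i],
               shared_features = paste0(shared, arrow[trends][seq_along(shared)],
                                        collapse = ", "),
               class_average_only = paste(only_avg, collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(row = integer(0), col = integer(0), classes = character(0),
               shared_features = character(0),
               class_average_only = character(0), stringsAsFactors = FALSE)
  class(out) <- c("multiclass_report", "data.frame")
  out
}

#' Per-class expression distribution of one miRNA
#'
#' Boxplot statistics (median, quartiles by linear interpolation, Tukey
#' whisker bounds clamped to the data range) of one feature's normalized
#' expression per combined class.
#'
#' @param x a normalized `expr_matrix`.
#' @param ontology a `sample_ontology`.
#' @param feature miRNA name.
#' @return Data frame with one row per class: `class`, `n`, `median`,
#'   `q1`, `q3`, `whisker_lo`, `whisker_hi`.
#' @export
expression_summary <- function(x, ontology, feature) {
  if (!feature %in% feature_names(x)) {
    stop_input("unknown feature: ", feature)
  }
  ont <- match_ontology(ontology, sample_ids(x))
  v <- x$values[, feature]
  out <- lapply(sort(unique(ont$class)), function(cl) {
    vals <- v[ont$class == cl]
    q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(vals[vals >= q[1] - 1.5 * iqr])
    hi <- max(vals[vals <= q[3] + 1.5 * iqr])
    data.frame(class = cl, n = length(vals), median = q[2], q1 = q[1],
               q3 = q[3], whisker_lo = lo, whisker_hi = hi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
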