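# small helper: a bmu_assignment from explicit coordinates
make_assign <- function(ids, row, col, som_dim = c(2, 2)) {
  out <- data.frame(sample_id = ids, row = row, col = col,
                    distance = 0, stringsAsFactors = FALSE)
  attr(out, "som_dim") <- som_dim
  class(out) <- c("bmu_assignment", "data.frame")
  out
}

test_that("nodes take strict-majority labels; ties and empties stay unlabelled", {
  ids <- paste0("S", 1:5)
  ont <- toy_ontology(ids, c("a", "a", "b", "a", "b"), c(1, 1, 1, 0, 0))
  # node (0,0): {a+, a+, b+} -> a+; node (0,1): {a-, b-} -> tie
  assign <- make_assign(ids, c(0, 0, 0, 0, 0), c(0, 0, 0, 1, 1))
  labels <- label_nodes(assign, ont)
  expect_identical(labels$labels[1, 1], "a+")
  expect_true(is.na(labels$labels[1, 2]))
  expect_true(all(is.na(labels$labels[2, ])))  # empty nodes
  expect_equal(sum(labels$counts), 5)
})

test_that("classification scores projections and handles unlabelled nodes", {
  # 10 test samples: 7 on correct nodes, 2 on a wrong-class node, 1 unlabelled
  train_ids <- paste0("T", 1:6)
  train_ont <- toy_ontology(train_ids, rep(c("breast", "skin", "lung"), each = 2),
                            rep(1, 6))
  train_assign <- make_assign(train_ids,
                              c(0, 0, 0, 0, 1, 1), c(0, 0, 1, 1, 0, 0))
  # (0,0): breast+ x2 ; (0,1): skin+ x2 ; (1,0): lung+ x2 ; (1,1): empty
  labels <- label_nodes(train_assign, train_ont)

  test_ids <- paste0("X", 1:10)
  test_ont <- toy_ontology(test_ids,
                           c(rep("breast", 4), rep("skin", 3), rep("lung", 3)),
                           rep(1, 10))
  test_assign <- make_assign(test_ids,
                             c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1),
                             c(0, 0, 0, 0, 1, 1, 1, 0, 0, 1))
  # breast x4 on (0,0) and skin x3 on (0,1): 7 correct; lung X8, X9 on the
  # breast node: 2 wrong; lung X10 on the empty node (1,1): unlabelled
  ev <- classify_samples(test_assign, labels, test_ont)
  expect_equal(unname(ev$accuracy["combined"]), 0.7)
  expect_equal(ev$n_unlabeled, 1)

  # wrong tissue but correct status still counts on the status axis
  one <- make_assign("X9", 0, 0)
  ev_one <- classify_samples(one, labels, test_ont[test_ont$sample_id == "X9", ])
  expect_equal(unname(ev_one$accuracy), c(0, 0, 1))

  # exclude mode drops unlabelled-node samples from scoring
  ev_ex <- classify_samples(test_assign, labels, test_ont,
                            unlabeled = "exclude")
  expect_equal(ev_ex$n_scored, 9)
  expect_equal(unname(ev_ex$accuracy["combined"]), 7 / 9)
})

test_that("perfect mappings yield unit accuracy and a diagonal confusion", {
  ids <- paste0("S", 1:8)
  ont <- toy_ontology(ids, rep(c("a", "b"), each = 4), rep(c(1, 0), 4))
  assign <- make_assign(ids,
                        rep(c(0, 1), each = 4),
                        rep(c(0, 1), 4))
  labels <- label_nodes(assign, ont)
  ev <- classify_samples(assign, labels, ont)
  expect_equal(unname(ev$accuracy), c(1, 1, 1))
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  conf <- ev$confusion
  expect_equal(sum(conf) - sum(diag(conf[, rownames(conf)])), 0)
})

test_that("confusion rows sum to class sizes with a dedicated UNLABELED column", {
  train_ids <- paste0("T", 1:6)
  train_ont <- toy_ontology(train_ids, rep(c("breast", "skin", "lung"), each = 2),
                            rep(1, 6))
  train_assign <- make_assign(train_ids,
                              c(0, 0, 0, 0, 1, 1), c(0, 0, 1, 1, 0, 0))
  labels <- label_nodes(train_assign, train_ont)
  test_ids <- paste0("X", 1:10)
  test_ont <- toy_ontology(test_ids,
                           c(rep("breast", 4), rep("skin", 3), rep("lung", 3)),
                           rep(1, 10))
  test_assign <- make_assign(test_ids,
                             c(0, 0, 0, 0, 0, 0, 0, 1, 0, 1),
                             c(0, 0, 0, 0, 1, 1, 1, 0, 0, 1))
  conf <- confusion_matrix(test_assign, labels, test_ont)
  expect_true("UNLABELED" %in% colnames(conf))
  expect_equal(unname(rowSums(conf)),
               as.vector(table(test_ont$class)[rownames(conf)]))
  expect_equal(sum(conf[, "UNLABELED"]), 1)
})

test_that("density maps count per node and add over disjoint subsets", {
  ids <- paste0("S", 1:4)
  assign <- make_assign(ids, c(0, 0, 0, 2), c(0, 0, 0, 1), som_dim = c(3, 2))
  d <- density_map(assign)
  expect_equal(d[1, 1], 3)
  expect_equal(d[3, 2], 1)
  expect_equal(sum(d), 4)
  d1 <- density_map(assign, subset = ids[1:2])
  d2 <- density_map(assign, subset = ids[3:4])
  expect_equal(d1 + d2, d)
})

test_that("multi-class nodes are reported with per-class rosters", {
  ids <- paste0("S", 1:6)
  ont <- toy_ontology(ids, c("a", "a", "a", "b", "c", "c"),
                      c(1, 1, 1, 1, 1, 1))
  assign <- make_assign(ids, rep(0, 6), rep(0, 6))
  nodes <- find_multiclass_nodes(assign, ont, min_classes = 3)
  expect_equal(nrow(nodes), 1)
  expect_equal(nodes$n_classes, 3)
  roster <- attr(nodes, "rosters")[["0,0"]]
  expect_equal(vapply(roster, length, 0L), c("a+" = 3L, "b+" = 1L, "c+" = 2L))

  # single-class cohort yields nothing at min_classes >= 2
  ont1 <- toy_ontology(ids, rep("a", 6), rep(1, 6))
  expect_equal(nrow(find_multiclass_nodes(assign, ont1, 2)), 0)

  # status filter restricts the roster
  ont2 <- toy_ontology(ids, c("a", "a", "b", "b", "c", "c"),
                       c(1, 0, 1, 0, 1, 0))
  n_neo <- find_multiclass_nodes(assign, ont2, 3, status = "neoplastic")
  expect_equal(n_neo$n_samples, 3)
})

test_that("majority labelling maximizes training accuracy (brute force)", {
  # exhaustive labelings on lattices <= 2x2 with <= 6 samples
  set.seed(42)
  classes <- c("a+", "b+", "c-")
  for (trial in 1:60) {
    n_nodes <- sample(1:4, 1)
    n <- sample(2:6, 1)
    node_of <- sample(seq_len(n_nodes), n, replace = TRUE)
    cls_of <- sample(classes, n, replace = TRUE)
    # brute force over all labelings (each node: any class or unlabelled)
    options <- c(classes, NA)
    grids <- do.call(expand.grid,
                     rep(list(seq_along(options)), n_nodes))
    best <- max(apply(grids, 1, function(g) {
      pred <- options[g[node_of]]
      sum(!is.na(pred) & pred == cls_of)
    }))
    # majority labelling score
    maj <- sum(vapply(seq_len(n_nodes), function(nd) {
      tab <- table(cls_of[node_of == nd])
      if (!length(tab)) return(0L)
      mx <- max(tab)
      if (sum(tab == mx) > 1) 0L else as.integer(mx)
    }, 0L))
    has_tie <- any(vapply(seq_len(n_nodes), function(nd) {
      tab <- table(cls_of[node_of == nd])
      length(tab) > 0 && sum(tab == max(tab)) > 1
    }, NA))
    if (has_tie) {
      expect_lte(maj, best)
    } else {
      expect_equal(maj, best)
    }
  }
})

test_that("projection inequality and confusion-derived rates hold on a fit", {
  r <- fit_fixture_model(seed = 21)
  labels <- label_nodes(r$model$train_assignment, r$pp$ontology)
  ev <- classify_samples(
    map_samples(r$model, r$pp$expression[r$pp$split$test_ids, ]),
    labels, r$pp$ontology)
  expect_lte(ev$accuracy["combined"], ev$accuracy["tissue"] + 1e-12)
  expect_lte(ev$accuracy["combined"], ev$accuracy["neoplastic"] + 1e-12)
  # sensitivity/specificity recomputed from the confusion matrix agree
  conf <- ev$confusion
  cls <- rownames(conf)
  neo_actual <- grepl("\\+$", cls)
  neo_pred <- grepl("\\+$", colnames(conf))
  sens <- sum(conf[neo_actual, neo_pred]) / sum(conf[neo_actual, ])
  spec <- sum(conf[!neo_actual, !neo_pred & colnames(conf) != "UNLABELED"]) /
    sum(conf[!neo_actual, ])
  expect_equal(ev$sensitivity, sens)
  expect_equal(ev$specificity, spec)
})
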