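planted_table <- function(n = 64, k = 6, seed = 1) {
  X <- random_literal_matrix(n, k, seed)
  y <- as.integer(X[, 1] == 1 & X[, 2] == -1)
  list(lit = cnnrules:::as_literal_table(X), X = X, y = y)
}

test_that("greedy induction recovers a planted conjunction exactly", {
  p <- planted_table()
  tree <- induce_tree(p$lit, p$y)
  pred <- predict_tree(tree, p$lit)
  expect_equal(pred, p$y)                        # 100% training fidelity
  expect_true(all(cnnrules:::tree_kernels_used(tree$root) %in% 1:2))
})

test_that("pure targets give a single leaf", {
  p <- planted_table()
  tree <- induce_tree(p$lit, rep(1L, 64))
  expect_identical(tree$root$type, "leaf")
  expect_identical(tree$root$class, 1L)
  rules <- tree_to_rules(tree)
  expect_length(rules$rules, 1)
  expect_equal(apply_rules(rules, p$lit), rep(1L, 64))
})

test_that("XOR targets cannot be separated at depth 1 but can at depth 2", {
  X <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1),
                             c = c(-1, 1), d = c(-1, 1)))
  lit <- cnnrules:::as_literal_table(X)
  y <- as.integer(X[, 1] != X[, 2])
  t1 <- induce_tree(lit, y, max_depth = 1)
  expect_lt(mean(predict_tree(t1, lit) == y), 1)
  t2 <- induce_tree(lit, y, max_depth = 2)
  expect_equal(predict_tree(t2, lit), y)
})

test_that("greedy trees track the exhaustive depth-3 optimum", {
  for (seed in 1:6) {
    set.seed(seed + 100)
    X <- random_literal_matrix(64, 6, seed + 100)
    y <- as.integer(runif(64) < plogis(X[, 1] + 0.8 * X[, 3] -
                                       0.6 * X[, 5]))
    lit <- cnnrules:::as_literal_table(X)
    tree <- induce_tree(lit, y, max_depth = 3, min_leaf = 1)
    greedy <- mean(predict_tree(tree, lit) == y)
    best <- oracle_best_tree_matches(X, y, 3) / nrow(X)
    expect_gte(greedy, best - 0.05)
  }
})

test_that("rule sets are mutually exclusive and exhaustive", {
  p <- planted_table(seed = 3)
  tree <- induce_tree(p$lit, p$y)
  rules <- tree_to_rules(tree)
  for (seed in 1:20) {
    X <- random_literal_matrix(50, 6, seed + 500)
    lit <- cnnrules:::as_literal_table(X)
    # apply_rules errors unless exactly one rule fires per row
    pred_rules <- apply_rules(rules, lit)
    pred_tree <- predict_tree(tree, lit)
    expect_equal(pred_rules, pred_tree)
  }
})

test_that("pruning collapses same-class subtrees and never grows the tree", {
  # two sibling leaves predicting the same class always merge
  X <- random_literal_matrix(40, 4, 9)
  y <- rep(c(0L, 1L), 20)
  lit <- cnnrules:::as_literal_table(X)
  tree <- induce_tree(lit, y, max_depth = 3, min_leaf = 1)
  pruned <- prune_tree(tree, lit, y)
  expect_lte(cnnrules:::tree_nodes(pruned$root),
             cnnrules:::tree_nodes(tree$root))

  # noisy planted rule: pruned tree no larger, validation fidelity kept
  set.seed(7)
  p <- planted_table(n = 200, seed = 7)
  y_noisy <- p$y
  flip <- sample(200, 10)
  y_noisy[flip] <- 1L - y_noisy[flip]
  fit <- 1:150
  val <- 151:200
  sub <- function(rows) cnnrules:::as_literal_table(p$X[rows, , drop = FALSE])
  tr <- induce_tree(sub(fit), y_noisy[fit], max_depth = 6, min_leaf = 1)
  pr <- prune_tree(tr, sub(val), y_noisy[val])
  expect_lte(cnnrules:::tree_nodes(pr$root), cnnrules:::tree_nodes(tr$root))
  fid_unpruned <- mean(predict_tree(tr, sub(val)) == y_noisy[val])
  fid_pruned <- mean(predict_tree(pr, sub(val)) == y_noisy[val])
  expect_gte(fid_pruned, fid_unpruned - 0.01)

  # empty validation split: warning, tree unchanged
  expect_warning(same <- prune_tree(tr, cnnrules:::as_literal_table(
    p$X[0, , drop = FALSE]), integer(0)), "empty")
  expect_identical(same$root, tr$root)
})

test_that("a depth-2 complete tree yields four path rules", {
  X <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1)))
  X <- X[rep(1:4, each = 4), ]
  lit <- cnnrules:::as_literal_table(X)
  y <- as.integer(X[, 1] != X[, 2])
  tree <- induce_tree(lit, y, max_depth = 2, min_leaf = 1)
  rules <- tree_to_rules(tree)
  expect_length(rules$rules, 4)
  expect_true(all(vapply(rules$rules, function(r) length(r$kernels),
                         integer(1)) == 2))
  # round trip: re-inducing from the rule set's own predictions
  # reproduces identical predictions
  pred <- apply_rules(rules, lit)
  tree2 <- induce_tree(lit, pred, max_depth = 2, min_leaf = 1)
  expect_equal(predict_tree(tree2, lit), pred)
})

test_that("evaluation reproduces the standard confusion formulas", {
  # constructed counts: TP=93 FN=7 TN=96 FP=4 per 100 images a class
  labels <- rep(c(1L, 0L), each = 100)
  pred <- c(rep(1L, 93), rep(0L, 7), rep(0L, 96), rep(1L, 4))
  cnn <- labels
  rep_ <- evaluate_rules(pred, NULL, labels, cnn)
  expect_equal(rep_$sensitivity, 0.930)
  expect_equal(rep_$specificity, 0.960)
  expect_equal(rep_$accuracy, (93 + 96) / 200)
  expect_equal(rep_$fidelity, mean(pred == labels))
  expect_equal(unname(rep_$confusion), c(93, 7, 96, 4))

  # fidelity is measured against the CNN, not the labels
  cnn2 <- pred
  expect_equal(evaluate_rules(pred, NULL, labels, cnn2)$fidelity, 1)
  expect_error(evaluate_rules(pred, NULL, labels[1:10], cnn), "align")
})

test_that("interventions respect allow/deny vocabularies", {
  p <- planted_table(seed = 21)
  iv0 <- intervene(p$lit, p$y)
  expect_equal(iv0$baseline_report$fidelity,
               iv0$constrained_report$fidelity)

  tree <- induce_tree(p$lit, p$y)
  root_kernel <- tree$root$kernel
  iv <- intervene(p$lit, p$y, deny = root_kernel)
  used <- iv$constrained$kernels_used
  expect_false(root_kernel %in% used)

  for (seed in 1:5) {
    set.seed(seed)
    deny <- sample(6, 2)
    ivr <- intervene(p$lit, p$y, deny = deny)
    expect_length(intersect(ivr$constrained$kernels_used, deny), 0)
  }
  expect_error(induce_tree(p$lit, p$y, denied_kernels = 1:6), "denied")
  expect_error(intervene(p$lit, p$y, allow = 1:2, deny = 2), "disjoint")
})

test_that("rule sets and trees export to JSON and DOT", {
  p <- planted_table(seed = 2)
  tree <- induce_tree(p$lit, p$y)
  rules <- tree_to_rules(tree)
  jpath <- tempfile(fileext = ".json")
  write_rules_json(rules, jpath)
  parsed <- jsonlite::read_json(jpath)
  expect_equal(length(parsed$rules), length(rules$rules))
  dpath <- tempfile(fileext = ".dot")
  write_tree_dot(tree, dpath)
  txt <- readLines(dpath)
  expect_true(grepl("digraph", txt[1]))
  expect_true(any(grepl("->", txt)))
})
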