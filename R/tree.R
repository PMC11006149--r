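# Decision-tree rule extraction over kernel literals: greedy Gini
# induction with a depth cap, reduced-error pruning, conversion of paths to
# conjunctive rules, rule application, evaluation and expert intervention.

gini_impurity <- function(y) {
  if (!length(y)) return(0)
  p <- mean(y == 1)
  2 * p * (1 - p)
}

majority_class <- function(y, tie = 0L) {
  n1 <- sum(y == 1); n0 <- length(y) - n1
  if (n1 > n0) 1L else if (n0 > n1) 0L else tie
}

leaf_node <- function(y, tie = 0L) {
  list(type = "leaf", class = majority_class(y, tie),
       counts = c(n0 = sum(y == 0), n1 = sum(y == 1)))
}

#' Induce a depth-capped decision tree over literals
#'
#' Greedy top-down growth: at each node the allowed kernel minimizing the
#' weighted Gini impurity of the two children (literal -1 vs +1) is chosen,
#' with ties broken by lowest kernel index. Growth stops at purity, the
#' depth limit, the minimum leaf size, or when no split reduces impurity.
#' No kernel repeats on a single path; leaves predict the majority class of
#' their training rows (ties predict class 0). Targets are normally the
#' CNN's own predictions, so the tree is a fidelity-first surrogate.
#'
#' @param literals a `literal_table`.
#' @param targets binary targets, typically `h(g(x))` CNN predictions.
#' @param max_depth maximum number of literals on any root-to-leaf path.
#' @param min_leaf minimum training rows in each child of a split.
#' @param allowed_kernels,denied_kernels optional kernel codes (or indices)
#'   restricting the vocabulary; they must be disjoint.
#' @return object of class `decision_tree`.
#' @export
induce_tree <- function(literals, targets, max_depth = 3L, min_leaf = 2L,
                        allowed_kernels = NULL, denied_kernels = NULL) {
  stopifnot(inherits(literals, "literal_table"))
  X <- literals$literals
  y <- check_binary(targets)
  if (nrow(X) == 0 || length(y) != nrow(X))
    stopf("literal table and targets must align and be non-empty")
  codes <- colnames(X)
  resolve <- function(k) {
    if (is.null(k)) return(integer(0))
    if (is.character(k)) {
      bad <- setdiff(k, codes)
      if (length(bad)) stopf("unknown kernel code(s): %s",
                             paste(bad, collapse = ", "))
      match(k, codes)
    } else as.integer(k)
  }
  allowed <- resolve(allowed_kernels)
  denied <- resolve(denied_kernels)
  if (length(intersect(allowed, denied)))
    stopf("allowed and denied kernels must be disjoint")
  vocab <- if (length(allowed)) sort(allowed) else seq_len(ncol(X))
  vocab <- setdiff(vocab, denied)
  if (!length(vocab)) stopf("all kernels denied: empty vocabulary")

  grow <- function(rows, depth, used) {
    yr <- y[rows]
    if (length(unique(yr)) <= 1 || depth >= max_depth)
      return(leaf_node(yr))
    cand <- setdiff(vocab, used)
    # choose the best split even at zero Gini gain (an XOR-style target has
    # no first split with positive gain); purity, depth and leaf-size
    # limits are the stopping rules
    best_k <- NA_integer_; best_gini <- Inf
    for (k in cand) {
      left <- rows[X[rows, k] == -1]
      right <- rows[X[rows, k] == 1]
      if (length(left) < min_leaf || length(right) < min_leaf) next
      wg <- (length(left) * gini_impurity(y[left]) +
             length(right) * gini_impurity(y[right])) / length(rows)
      if (wg < best_gini) { best_gini <- wg; best_k <- k }
    }
    if (is.na(best_k)) return(leaf_node(yr))
    left <- rows[X[rows, best_k] == -1]
    right <- rows[X[rows, best_k] == 1]
    list(type = "split", kernel = best_k, code = codes[best_k],
         counts = c(n0 = sum(yr == 0), n1 = sum(yr == 1)),
         neg = grow(left, depth + 1L, c(used, best_k)),
         pos = grow(right, depth + 1L, c(used, best_k)))
  }
  root <- grow(seq_len(nrow(X)), 0L, integer(0))
  structure(list(root = root, max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf), kernel_codes = codes,
                 denied = denied, vocabulary = vocab),
            class = "decision_tree")
}

tree_nodes <- function(node) {
  if (node$type == "leaf") 1L
  else 1L + tree_nodes(node$neg) + tree_nodes(node$pos)
}

tree_kernels_used <- function(node) {
  if (node$type == "leaf") return(integer(0))
  sort(unique(c(node$kernel, tree_kernels_used(node$neg),
                tree_kernels_used(node$pos))))
}

#' Predict classes by tree traversal
#'
#' @param tree a `decision_tree`.
#' @param literals a `literal_table` covering the tree's kernels.
#' @return integer vector of 0/1 predictions.
#' @export
predict_tree <- function(tree, literals) {
  stopifnot(inherits(tree, "decision_tree"),
            inherits(literals, "literal_table"))
  X <- literals$literals
  used <- tree_kernels_used(tree$root)
  if (length(used) && max(used) > ncol(X))
    stopf("literal table has %d kernels but tree uses kernel %d",
          ncol(X), max(used))
  walk <- function(node, rows, out) {
    if (node$type == "leaf") { out[rows] <- node$class; return(out) }
    neg <- rows[X[rows, node$kernel] == -1]
    pos <- rows[X[rows, node$kernel] == 1]
    out <- walk(node$neg, neg, out)
    walk(node$pos, pos, out)
  }
  walk(tree$root, seq_len(nrow(X)), integer(nrow(X)))
}

#' Reduced-error pruning on a validation split
#'
#' Bottom-up, a subtree is collapsed to a leaf predicting the majority of
#' its training rows whenever that does not increase the number of
#' misclassified validation rows reaching the node (so two sibling leaves
#' predicting the same class always merge). The validation split must be
#' disjoint from the induction split.
#'
#' @param tree a `decision_tree`.
#' @param literals validation `literal_table`.
#' @param targets validation binary targets (same definition as used for
#'   induction, normally CNN predictions).
#' @return the pruned `decision_tree`.
#' @export
prune_tree <- function(tree, literals, targets) {
  stopifnot(inherits(tree, "decision_tree"))
  if (is.null(literals) || nrow(literals$literals) == 0) {
    warning("empty validation split: pruning skipped", call. = FALSE)
    return(tree)
  }
  X <- literals$literals
  y <- check_binary(targets)
  prune <- function(node, rows) {
    if (node$type == "leaf") return(node)
    node$neg <- prune(node$neg, rows[X[rows, node$kernel] == -1])
    node$pos <- prune(node$pos, rows[X[rows, node$kernel] == 1])
    leaf_class <- if (node$counts["n1"] > node$counts["n0"]) 1L
                  else if (node$counts["n0"] > node$counts["n1"]) 0L else 0L
    sub_pred <- predict_node(node, X, rows)
    err_sub <- sum(sub_pred != y[rows])
    err_leaf <- sum(leaf_class != y[rows])
    if (err_leaf <= err_sub)
      list(type = "leaf", class = leaf_class, counts = node$counts)
    else node
  }
  tree$root <- prune(tree$root, seq_len(nrow(X)))
  tree
}

predict_node <- function(node, X, rows) {
  out <- integer(length(rows))
  names(out) <- rows
  walk <- function(nd, rr) {
    if (!length(rr)) return()
    if (nd$type == "leaf") { out[as.character(rr)] <<- nd$class; return() }
    walk(nd$neg, rr[X[rr, nd$kernel] == -1])
    walk(nd$pos, rr[X[rr, nd$kernel] == 1])
  }
  walk(node, rows)
  unname(out)
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(sprintf("decision_tree: %d nodes, max depth %d, kernels {%s}\n",
              tree_nodes(x$root), x$max_depth,
              paste(x$kernel_codes[tree_kernels_used(x$root)],
                    collapse = ", ")))
  invisible(x)
}

#' Convert a tree to a conjunctive rule set
#'
#' One rule per leaf: the body is the conjunction of signed literals along
#' the root-to-leaf path (negative branch contributes a negated literal),
#' the head is the leaf's predicted class. The rules are mutually exclusive
#' and exhaustive by construction. Support is the number of training rows
#' at the leaf and confidence the fraction of them matching the head.
#'
#' @param tree a `decision_tree`.
#' @return object of class `rule_set`.
#' @export
tree_to_rules <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  rules <- list()
  walk <- function(node, kernels, signs) {
    if (node$type == "leaf") {
      n <- sum(node$counts)
      conf <- if (n > 0) unname(node$counts[paste0("n", node$class)]) / n
              else NA_real_
      rules[[length(rules) + 1L]] <<- list(
        kernels = kernels, signs = signs,
        codes = tree$kernel_codes[kernels],
        head = node$class, support = n, confidence = conf)
      return()
    }
    walk(node$neg, c(kernels, node$kernel), c(signs, -1L))
    walk(node$pos, c(kernels, node$kernel), c(signs, 1L))
  }
  walk(tree$root, integer(0), integer(0))
  structure(list(rules = rules, kernel_codes = tree$kernel_codes,
                 kernels_used = tree_kernels_used(tree$root),
                 max_depth = tree$max_depth),
            class = "rule_set")
}

format_rule <- function(rule) {
  body <- if (length(rule$kernels))
    paste(ifelse(rule$signs == 1, rule$codes, paste0("¬", rule$codes)),
          collapse = " ∧ ")
  else "TRUE"
  head <- if (rule$head == 1) "Effusion" else "Healthy"
  sprintf("%s → %s  [support %d, confidence %.2f]",
          body, head, rule$support, rule$confidence)
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("rule_set: %d rules over kernels {%s}\n", length(x$rules),
              paste(x$kernel_codes[x$kernels_used], collapse = ", ")))
  for (r in x$rules) cat(" ", format_rule(r), "\n")
  invisible(x)
}

#' Apply a rule set to a literal table
#'
#' Each image must satisfy exactly one rule body; that rule's head is the
#' prediction. Implemented by direct conjunction matching (independently of
#' tree traversal).
#'
#' @param rules a `rule_set`.
#' @param literals a `literal_table` covering all kernels in rule bodies.
#' @return integer vector of 0/1 predictions.
#' @export
apply_rules <- function(rules, literals) {
  stopifnot(inherits(rules, "rule_set"), inherits(literals, "literal_table"))
  X <- literals$literals
  if (length(rules$kernels_used) && max(rules$kernels_used) > ncol(X))
    stopf("literal table is missing kernel column %d",
          max(rules$kernels_used))
  n <- nrow(X)
  pred <- rep(NA_integer_, n)
  fired <- integer(n)
  for (r in rules$rules) {
    sat <- rep(TRUE, n)
    for (j in seq_along(r$kernels))
      sat <- sat & (X[, r$kernels[j]] == r$signs[j])
    fired[sat] <- fired[sat] + 1L
    pred[sat] <- r$head
  }
  if (any(fired != 1L))
    stopf("rule set is not mutually exclusive/exhaustive on this table")
  pred
}

#' Evaluate a rule set: accuracy, fidelity, sensitivity, specificity
#'
#' Accuracy, sensitivity and specificity are computed against ground-truth
#' labels (class 1 = positive, e.g. effusion; sensitivity is recall of
#' class 1). Fidelity is the fraction of rule predictions that match the
#' CNN's own predictions, not the labels.
#'
#' @param rules a `rule_set` (or precomputed integer predictions).
#' @param literals `literal_table` to predict on (ignored when `rules` is
#'   already a prediction vector).
#' @param labels ground-truth 0/1 labels.
#' @param cnn_predictions the CNN's 0/1 predictions on the same images.
#' @param split optional split identifier recorded in the report.
#' @return object of class `evaluation_report`.
#' @export
evaluate_rules <- function(rules, literals, labels, cnn_predictions,
                           split = NA_character_) {
  pred <- if (is.numeric(rules) || is.integer(rules)) as.integer(rules)
          else apply_rules(rules, literals)
  labels <- check_binary(labels, "labels")
  cnn_predictions <- check_binary(cnn_predictions, "cnn_predictions")
  if (length(pred) != length(labels) ||
      length(pred) != length(cnn_predictions))
    stopf("predictions (%d), labels (%d) and cnn_predictions (%d) must align",
          length(pred), length(labels), length(cnn_predictions))
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  structure(list(
    split = split, n = length(pred),
    confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
    accuracy = (tp + tn) / length(pred),
    fidelity = mean(pred == cnn_predictions),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("evaluation_report [%s, n=%d]: accuracy %.3f, ",
                     "fidelity %.3f, sensitivity %.3f, specificity %.3f\n"),
              x$split, x$n, x$accuracy, x$fidelity, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' Re-induce rules under an expert-constrained kernel vocabulary
#'
#' The what-if intervention: rules are re-induced with the vocabulary
#' restricted by allow/deny kernel lists and evaluated side by side with
#' the unconstrained baseline, reproducing the expert workflow of swapping
#' kernels in and out of the explanation.
#'
#' @param literals training `literal_table`.
#' @param cnn_predictions CNN predictions used as induction targets.
#' @param allow,deny kernel codes or indices (disjoint); empty allow means
#'   all kernels.
#' @param max_depth,min_leaf tree settings, as in [induce_tree()].
#' @param labels optional ground-truth labels for the reports.
#' @return object of class `intervention`: baseline and constrained
#'   `rule_set`s plus `evaluation_report`s.
#' @export
intervene <- function(literals, cnn_predictions, allow = NULL, deny = NULL,
                      max_depth = 3L, min_leaf = 2L, labels = NULL) {
  base_tree <- induce_tree(literals, cnn_predictions, max_depth = max_depth,
                           min_leaf = min_leaf)
  cons_tree <- induce_tree(literals, cnn_predictions, max_depth = max_depth,
                           min_leaf = min_leaf, allowed_kernels = allow,
                           denied_kernels = deny)
  base_rules <- tree_to_rules(base_tree)
  cons_rules <- tree_to_rules(cons_tree)
  lab <- labels %||% literals$labels %||% cnn_predictions
  structure(list(
    baseline = base_rules, constrained = cons_rules,
    baseline_report = evaluate_rules(base_rules, literals, lab,
                                     cnn_predictions, "train"),
    constrained_report = evaluate_rules(cons_rules, literals, lab,
                                        cnn_predictions, "train"),
    allow = allow, deny = deny
  ), class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  cat("intervention (baseline vs constrained vocabulary)\n baseline:   ")
  print(x$baseline_report)
  cat(" constrained: ")
  print(x$constrained_report)
  invisible(x)
}

#' Export a rule set as JSON
#'
#' @param rules a `rule_set`.
#' @param path output path.
#' @export
write_rules_json <- function(rules, path) {
  stopifnot(inherits(rules, "rule_set"))
  obj <- list(
    max_depth = rules$max_depth,
    kernels_used = rules$kernel_codes[rules$kernels_used],
    rules = lapply(rules$rules, function(r) list(
      body = lapply(seq_along(r$kernels), function(j) list(
        kernel = r$codes[j], sign = r$signs[j])),
      head = r$head, support = r$support, confidence = r$confidence))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a decision tree as Graphviz DOT
#'
#' @param tree a `decision_tree`.
#' @param path output path.
#' @export
write_tree_dot <- function(tree, path) {
  stopifnot(inherits(tree, "decision_tree"))
  lines <- c("digraph rules {", "  node [shape=box];")
  counter <- 0L
  emit <- function(node) {
    counter <<- counter + 1L
    id <- sprintf("n%d", counter)
    if (node$type == "leaf") {
      lines <<- c(lines, sprintf(
        "  %s [label=\"%s\\n(%d/%d)\", shape=ellipse];", id,
        if (node$class == 1) "Effusion" else "Healthy",
        node$counts["n0"], node$counts["n1"]))
    } else {
      lines <<- c(lines, sprintf("  %s [label=\"%s\"];", id, node$code))
      nid <- emit(node$neg)
      pid <- emit(node$pos)
      lines <<- c(lines,
                  sprintf("  %s -> %s [label=\"¬%s\"];", id, nid, node$code),
                  sprintf("  %s -> %s [label=\"%s\"];", id, pid, node$code))
    }
    id
  }
  emit(tree$root)
  writeLines(c(lines, "}"), path)
  invisible(path)
}
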