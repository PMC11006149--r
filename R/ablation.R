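# Kernel-group relevance experiments: incremental activation against
# random uninterpretable baselines, single-region muting, ranking of
# region combinations and a random muting curve. Accuracy is measured
# against ground-truth labels on the supplied dataset (the training split
# by default). All conditions reuse one extracted activation set, so each
# mask evaluation is a single pass of the classifier head.

#' Group kernels by their assigned anatomical region
#'
#' @param concepts a `concept_map`.
#' @return object of class `kernel_groups`: named list `groups` (region ->
#'   kernel ids) and `uninterpretable` kernel ids. Groups are pairwise
#'   disjoint with each other and the uninterpretable set by construction.
#' @export
kernel_groups <- function(concepts) {
  stopifnot(inherits(concepts, "concept_map"))
  a <- concepts$assignment
  interp <- a$region != UNINTERPRETABLE
  groups <- split(a$kernel[interp], a$region[interp])
  structure(list(groups = groups,
                 uninterpretable = a$kernel[!interp],
                 n_kernels = nrow(a)),
            class = "kernel_groups")
}

#' @export
print.kernel_groups <- function(x, ...) {
  cat(sprintf("kernel_groups: %d regions, %d uninterpretable of %d kernels\n",
              length(x$groups), length(x$uninterpretable), x$n_kernels))
  for (r in names(x$groups))
    cat(sprintf("  %s: %s\n", r, paste(x$groups[[r]], collapse = ", ")))
  invisible(x)
}

validate_groups <- function(groups) {
  stopifnot(inherits(groups, "kernel_groups"))
  ids <- unlist(groups$groups, use.names = FALSE)
  if (anyDuplicated(c(ids, groups$uninterpretable)))
    stopf("kernel groups must be pairwise disjoint (and disjoint from the uninterpretable set)")
  if (length(ids) && max(c(ids, groups$uninterpretable)) > groups$n_kernels)
    stopf("group kernel ids exceed the kernel count")
  invisible(groups)
}

# accuracy of the model under an activate-only / mute mask, from cached
# activations
masked_accuracy <- function(model, activations, labels, keep_ids,
                            mode = "activate_only") {
  mask <- kernel_mask(keep_ids, mode = mode, n_kernels = model$n_kernels)
  mean(predict_from_activations(model, activations, mask) == labels)
}

ablation_df <- function(experiment, condition, replicate, accuracy,
                        n_kernels, total) {
  data.frame(experiment = experiment, condition = condition,
             replicate = replicate, accuracy = accuracy,
             n_kernels = n_kernels,
             pct_kernels = 100 * n_kernels / total,
             stringsAsFactors = FALSE)
}

#' Incremental activation of region kernel groups vs random baselines
#'
#' For each prefix of `order`, only the kernels of those regions are kept
#' active (everything else muted) and accuracy is recorded; a paired
#' baseline activates `n_reps` random subsets of uninterpretable kernels of
#' equal size (sampled without replacement). Reference conditions report
#' the unmasked model (`all_kernels`) and the uninterpretable-only mask.
#'
#' @param model a `feature_model`.
#' @param dataset a `phantom_dataset` (accuracy vs its labels).
#' @param groups a `kernel_groups`.
#' @param order regions to activate incrementally (default: all groups,
#'   name order).
#' @param n_reps random-baseline repetitions per prefix size.
#' @param seed integer seed for the baseline draws.
#' @param activations optional precomputed `activation_set`.
#' @return `ablation_result` data.frame (experiment, condition, replicate,
#'   accuracy, n_kernels, pct_kernels).
#' @export
incremental_activation <- function(model, dataset, groups,
                                   order = names(groups$groups),
                                   n_reps = 100L, seed = 1L,
                                   activations = NULL) {
  validate_groups(groups)
  if (!all(order %in% names(groups$groups)))
    stopf("order must name existing groups")
  acts <- activations %||% extract_activations(model, dataset)
  labels <- dataset$labels
  K <- model$n_kernels
  set.seed(seed)
  out <- list()
  out[[1]] <- ablation_df("incremental_activation", "all_kernels", 0L,
                          masked_accuracy(model, acts, labels, seq_len(K)),
                          K, K)
  out[[2]] <- ablation_df("incremental_activation", "uninterpretable_only",
                          0L,
                          masked_accuracy(model, acts, labels,
                                          groups$uninterpretable),
                          length(groups$uninterpretable), K)
  for (p in seq_along(order)) {
    ids <- sort(unlist(groups$groups[order[seq_len(p)]], use.names = FALSE))
    cond <- paste0("prefix_", p, ":", paste(order[seq_len(p)],
                                            collapse = "+"))
    out[[length(out) + 1]] <- ablation_df(
      "incremental_activation", cond, 0L,
      masked_accuracy(model, acts, labels, ids), length(ids), K)
    if (length(ids) > length(groups$uninterpretable))
      stopf("baseline needs %d uninterpretable kernels but only %d exist",
            length(ids), length(groups$uninterpretable))
    for (rep in seq_len(n_reps)) {
      rnd <- sample(groups$uninterpretable, length(ids))
      out[[length(out) + 1]] <- ablation_df(
        "incremental_activation", paste0("random_baseline_", p), rep,
        masked_accuracy(model, acts, labels, rnd), length(ids), K)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "seed") <- seed
  class(res) <- c("ablation_result", class(res))
  res
}

#' Mute one region's kernels together with all uninterpretable kernels
#'
#' For each region R the mask mutes (uninterpretable union group R); the
#' reference condition mutes the uninterpretable kernels only. The drop of
#' a region's accuracy below the reference measures how much the remaining
#' interpretable kernels depend on R.
#'
#' @inheritParams incremental_activation
#' @return `ablation_result` data.frame.
#' @export
single_region_muting <- function(model, dataset, groups,
                                 activations = NULL) {
  validate_groups(groups)
  if (!length(groups$groups)) stopf("no kernel groups to mute")
  acts <- activations %||% extract_activations(model, dataset)
  labels <- dataset$labels
  K <- model$n_kernels
  out <- list(ablation_df(
    "single_region_muting", "reference_uninterpretable_muted", 0L,
    masked_accuracy(model, acts, labels, groups$uninterpretable,
                    mode = "mute"),
    K - length(groups$uninterpretable), K))
  for (r in names(groups$groups)) {
    muted <- c(groups$uninterpretable, groups$groups[[r]])
    out[[length(out) + 1]] <- ablation_df(
      "single_region_muting", paste0("muted_", r), 0L,
      masked_accuracy(model, acts, labels, muted, mode = "mute"),
      K - length(muted), K)
  }
  res <- do.call(rbind, out)
  class(res) <- c("ablation_result", class(res))
  res
}

#' Rank combinations of region groups by activated-only accuracy
#'
#' Evaluates the model with only the kernels of each size-`choose`
#' combination of regions active and returns the `top_k` combinations by
#' accuracy (ties break by combination name for determinism).
#'
#' @inheritParams incremental_activation
#' @param choose combination size.
#' @param top_k combinations to return.
#' @param max_evals hard cap on the number of evaluated combinations.
#' @return `ablation_result` data.frame, ranked.
#' @export
combination_ranking <- function(model, dataset, groups, choose = 4L,
                                top_k = 20L, max_evals = 5000L,
                                activations = NULL) {
  validate_groups(groups)
  rn <- names(groups$groups)
  if (length(rn) < choose)
    stopf("need at least %d groups, have %d", choose, length(rn))
  combos <- utils::combn(rn, choose, simplify = FALSE)
  if (length(combos) > max_evals)
    stopf("%d combinations exceed max_evals = %d; restrict the groups",
          length(combos), max_evals)
  acts <- activations %||% extract_activations(model, dataset)
  labels <- dataset$labels
  K <- model$n_kernels
  rows <- lapply(combos, function(cb) {
    ids <- sort(unlist(groups$groups[cb], use.names = FALSE))
    ablation_df("combination_ranking", paste(cb, collapse = "+"), 0L,
                masked_accuracy(model, acts, labels, ids), length(ids), K)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$accuracy, res$condition), ]
  res <- utils::head(res, top_k)
  rownames(res) <- NULL
  class(res) <- c("ablation_result", class(res))
  res
}

#' Accuracy under random muting of increasing kernel fractions
#'
#' For each fraction f, `n_reps` random subsets of `round(f * K)` kernels
#' are muted and accuracy recorded. Fractions 0 and 1 are allowed as exact
#' limits (unmasked model; all kernels muted).
#'
#' @inheritParams incremental_activation
#' @param fractions muted-kernel fractions in \[0, 1\].
#' @param n_reps replicates per fraction.
#' @return `ablation_result` data.frame.
#' @export
random_muting_curve <- function(model, dataset, groups = NULL,
                                fractions = seq(0.1, 0.9, by = 0.1),
                                n_reps = 20L, seed = 1L,
                                activations = NULL) {
  if (any(fractions < 0 | fractions > 1))
    stopf("fractions must lie in [0, 1]")
  acts <- activations %||% extract_activations(model, dataset)
  labels <- dataset$labels
  K <- model$n_kernels
  set.seed(seed)
  out <- list()
  for (f in fractions) {
    m <- round(f * K)
    reps <- if (m == 0 || m == K) 1L else n_reps
    for (rep in seq_len(reps)) {
      muted <- if (m == 0) integer(0) else sort(sample(K, m))
      out[[length(out) + 1]] <- ablation_df(
        "random_muting_curve", sprintf("fraction_%.2f", f), rep,
        masked_accuracy(model, acts, labels, muted, mode = "mute"),
        K - m, K)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "seed") <- seed
  class(res) <- c("ablation_result", class(res))
  res
}

#' Write an ablation result as tidy CSV
#'
#' @param result an `ablation_result`.
#' @param path output CSV path.
#' @export
write_ablation_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
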