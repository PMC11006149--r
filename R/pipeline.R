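# End-to-end pipeline: phantom -> train -> activations -> quantization ->
# concepts -> vocabulary filtering -> rule induction/pruning -> evaluation
# -> ablation -> radiomics, with artifact export and a what-if entry point.
# Stages are individually callable on a bundle so the CLI can run them
# step by step; run_pipeline() chains them.

#' Pipeline configuration
#'
#' Collects the settings of every stage. All randomness derives from
#' `seed`: the phantom uses `seed`, the validation phantom `seed + 1`,
#' training `seed + 2`, the induction/pruning fold split `seed + 3` and the
#' ablation baselines `seed + 4`.
#'
#' @param phantom a [phantom_config()]; its `seed` is overridden by `seed`.
#' @param val_n_per_class images per class in the held-out validation set.
#' @param arch an [arch_config()].
#' @param train list: `epochs`, `batch_size`, `lr`, `min_val_acc`.
#' @param tree list: `max_depth`, `min_leaf`, `prune_fraction` (fraction of
#'   training rows held out for reduced-error pruning).
#' @param concepts list: `iou_min`, `hit_frac`, `max_regions`,
#'   `percentile`, `interp`.
#' @param ablation list: `n_reps` (incremental baselines), `curve_reps`,
#'   `combo_choose`, `top_k`.
#' @param radiomics list: `n_gray`.
#' @param filter_uninterpretable restrict the rule vocabulary to
#'   interpretable kernels (the clinically-relevant rule set); when FALSE
#'   rules may use uninterpretable kernels.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            val_n_per_class = 40L,
                            arch = arch_config(input_size = phantom$image_size),
                            train = list(),
                            tree = list(),
                            concepts = list(),
                            ablation = list(),
                            radiomics = list(),
                            filter_uninterpretable = TRUE,
                            seed = 1L) {
  defaults <- function(x, d) utils::modifyList(d, x)
  cfg <- structure(list(
    phantom = phantom, val_n_per_class = as.integer(val_n_per_class),
    arch = arch,
    train = defaults(train, list(epochs = 20L, batch_size = 32L, lr = 3e-3,
                                 min_val_acc = 0.7)),
    tree = defaults(tree, list(max_depth = 3L, min_leaf = 2L,
                               prune_fraction = 0.2)),
    concepts = defaults(concepts, list(iou_min = 0.5, hit_frac = 0.70,
                                       max_regions = 2L, percentile = 95,
                                       interp = "bilinear")),
    ablation = defaults(ablation, list(n_reps = 100L, curve_reps = 20L,
                                       combo_choose = 4L, top_k = 20L)),
    radiomics = defaults(radiomics, list(n_gray = 32L)),
    filter_uninterpretable = isTRUE(filter_uninterpretable),
    seed = as.integer(seed)
  ), class = "pipeline_config")
  if (arch$input_size != phantom$image_size)
    stopf("arch input_size (%d) must match phantom image_size (%d)",
          arch$input_size, phantom$image_size)
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full extraction pipeline
#'
#' Executes every stage on a fresh bundle and, when `out_dir` is given,
#' writes all artifacts (CSV tables, rule JSON, tree DOT files, a manifest
#' with the config hash and a human-readable summary). Idempotent given
#' the config: identical runs produce identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return a `pipeline_run` bundle (list of every intermediate object).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- list(config = config, hash = config_hash(config))
  bundle <- with_stage("generate", stage_generate(bundle))
  bundle <- with_stage("train", stage_train(bundle))
  bundle <- with_stage("quantize", stage_quantize(bundle))
  bundle <- with_stage("concepts", stage_concepts(bundle))
  bundle <- with_stage("rules", stage_rules(bundle))
  bundle <- with_stage("ablation", stage_ablation(bundle))
  bundle <- with_stage("radiomics", stage_radiomics(bundle))
  class(bundle) <- "pipeline_run"
  if (!is.null(out_dir)) write_pipeline_artifacts(bundle, out_dir)
  bundle
}

#' @rdname run_pipeline
#' @param bundle a pipeline bundle (list with at least `config`).
#' @export
stage_generate <- function(bundle) {
  cfg <- bundle$config
  ph <- cfg$phantom
  ph$seed <- cfg$seed
  val_ph <- ph
  val_ph$n_per_class <- cfg$val_n_per_class
  val_ph$seed <- cfg$seed + 1L
  bundle$train_data <- generate_dataset(ph)
  bundle$val_data <- generate_dataset(val_ph)
  bundle
}

#' @rdname run_pipeline
#' @export
stage_train <- function(bundle) {
  cfg <- bundle$config
  tr <- cfg$train
  bundle$model <- train_tiny_cnn(bundle$train_data, arch = cfg$arch,
                                 seed = cfg$seed + 2L, epochs = tr$epochs,
                                 batch_size = tr$batch_size, lr = tr$lr,
                                 val_dataset = bundle$val_data,
                                 min_val_acc = tr$min_val_acc)
  bundle
}

#' @rdname run_pipeline
#' @export
stage_quantize <- function(bundle) {
  bundle$acts_train <- extract_activations(bundle$model, bundle$train_data)
  bundle$acts_val <- extract_activations(bundle$model, bundle$val_data)
  bundle$norms_train <- kernel_norms(bundle$acts_train,
                                     labels = bundle$train_data$labels)
  bundle$norms_val <- kernel_norms(bundle$acts_val,
                                   labels = bundle$val_data$labels)
  bundle$thresholds <- compute_thresholds(bundle$norms_train)
  bundle$literals_train <- binarize(bundle$norms_train, bundle$thresholds)
  bundle$literals_val <- binarize(bundle$norms_val, bundle$thresholds)
  bundle$cnn_pred_train <- cnn_predict(bundle$model, bundle$train_data)
  bundle$cnn_pred_val <- cnn_predict(bundle$model, bundle$val_data)
  bundle
}

#' @rdname run_pipeline
#' @export
stage_concepts <- function(bundle) {
  cc <- bundle$config$concepts
  bundle$concepts <- assign_concepts(
    bundle$acts_train, bundle$train_data$boxes, iou_min = cc$iou_min,
    hit_frac = cc$hit_frac, max_regions = cc$max_regions,
    percentile = cc$percentile, interp = cc$interp,
    image_size = bundle$config$phantom$image_size)
  bundle$groups <- kernel_groups(bundle$concepts)
  bundle
}

# induce on a (1 - prune_fraction) fold, reduced-error prune on the rest
induce_and_prune <- function(literals, targets, tree_cfg, seed) {
  n <- nrow(literals$literals)
  set.seed(seed)
  n_prune <- round(tree_cfg$prune_fraction * n)
  prune_rows <- if (n_prune > 0) sort(sample(n, n_prune)) else integer(0)
  fit_rows <- setdiff(seq_len(n), prune_rows)
  subset_lit <- function(rows) {
    out <- literals
    out$literals <- literals$literals[rows, , drop = FALSE]
    out$image_ids <- literals$image_ids[rows]
    out$labels <- literals$labels[rows]
    out
  }
  tree <- induce_tree(subset_lit(fit_rows), targets[fit_rows],
                      max_depth = tree_cfg$max_depth,
                      min_leaf = tree_cfg$min_leaf)
  if (length(prune_rows))
    tree <- prune_tree(tree, subset_lit(prune_rows), targets[prune_rows])
  tree
}

#' @rdname run_pipeline
#' @export
stage_rules <- function(bundle) {
  cfg <- bundle$config
  lit_train <- bundle$literals_train
  lit_val <- bundle$literals_val
  # baseline: full kernel vocabulary (may include uninterpretable kernels)
  bundle$baseline_tree <- induce_and_prune(lit_train, bundle$cnn_pred_train,
                                           cfg$tree, cfg$seed + 3L)
  bundle$baseline_rules <- tree_to_rules(bundle$baseline_tree)
  if (cfg$filter_uninterpretable &&
      length(interpretable_kernels(bundle$concepts)) > 0) {
    flit_train <- filter_interpretable(lit_train, bundle$concepts)
    flit_val <- filter_interpretable(lit_val, bundle$concepts)
  } else {
    flit_train <- lit_train
    flit_val <- lit_val
  }
  bundle$final_literals_train <- flit_train
  bundle$final_literals_val <- flit_val
  bundle$final_tree <- induce_and_prune(flit_train, bundle$cnn_pred_train,
                                        cfg$tree, cfg$seed + 3L)
  bundle$final_rules <- tree_to_rules(bundle$final_tree)
  ev <- function(rules, lt, lv) list(
    train = evaluate_rules(rules, lt, bundle$train_data$labels,
                           bundle$cnn_pred_train, "train"),
    validation = evaluate_rules(rules, lv, bundle$val_data$labels,
                                bundle$cnn_pred_val, "validation"))
  bundle$baseline_eval <- ev(bundle$baseline_rules, lit_train, lit_val)
  bundle$final_eval <- ev(bundle$final_rules, flit_train, flit_val)
  bundle$cnn_eval <- list(
    train = evaluate_rules(bundle$cnn_pred_train, NULL,
                           bundle$train_data$labels, bundle$cnn_pred_train,
                           "train"),
    validation = evaluate_rules(bundle$cnn_pred_val, NULL,
                                bundle$val_data$labels, bundle$cnn_pred_val,
                                "validation"))
  bundle
}

#' @rdname run_pipeline
#' @export
stage_ablation <- function(bundle) {
  cfg <- bundle$config
  ab <- cfg$ablation
  groups <- bundle$groups
  acts <- bundle$acts_train
  res <- list()
  if (length(groups$groups) >= 1 && length(groups$uninterpretable) >= 1) {
    # incremental baselines need enough uninterpretable kernels; activate
    # groups in increasing-size order and stop before exhausting them
    order_ok <- names(sort(lengths(groups$groups)))
    sizes <- cumsum(lengths(groups$groups)[order_ok])
    n_feasible <- sum(sizes <= length(groups$uninterpretable))
    if (n_feasible >= 1) {
      res$incremental <- incremental_activation(
        bundle$model, bundle$train_data, groups,
        order = order_ok[seq_len(n_feasible)],
        n_reps = ab$n_reps, seed = cfg$seed + 4L, activations = acts)
    }
  }
  if (length(groups$groups) >= 1)
    res$single_muting <- single_region_muting(bundle$model,
                                              bundle$train_data, groups,
                                              activations = acts)
  choose <- min(ab$combo_choose, length(groups$groups))
  if (choose >= 2)
    res$combinations <- combination_ranking(bundle$model, bundle$train_data,
                                            groups, choose = choose,
                                            top_k = ab$top_k,
                                            activations = acts)
  res$random_curve <- random_muting_curve(
    bundle$model, bundle$train_data, groups,
    fractions = c(0, seq(0.1, 0.9, by = 0.1), 1),
    n_reps = ab$curve_reps, seed = cfg$seed + 4L, activations = acts)
  bundle$ablation <- res
  bundle
}

#' @rdname run_pipeline
#' @export
stage_radiomics <- function(bundle) {
  cfg <- bundle$config
  assigned <- bundle$concepts$assignment
  interp <- assigned[assigned$region != UNINTERPRETABLE, , drop = FALSE]
  regions <- unique(interp$region)
  if (!length(regions)) {
    bundle$features <- NULL
    bundle$correlations <- NULL
    return(bundle)
  }
  bundle$features <- feature_table(bundle$train_data, regions = regions,
                                   n_gray = cfg$radiomics$n_gray)
  rows <- list()
  for (i in seq_len(nrow(interp))) {
    for (feat in radiomics_feature_ids) {
      cr <- correlate_norms(bundle$norms_train, bundle$features,
                            kernel = interp$kernel[i],
                            region = interp$region[i], feature = feat)
      rows[[length(rows) + 1]] <- data.frame(
        kernel = cr$kernel, region = cr$region, feature = feat,
        r = cr$r, n = cr$n, stringsAsFactors = FALSE)
    }
  }
  bundle$correlations <- do.call(rbind, rows)
  bundle
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run (seed %d, config %s)\n", x$config$seed, x$hash))
  if (!is.null(x$model)) print(x$model)
  if (!is.null(x$concepts)) print(x$concepts)
  if (!is.null(x$final_eval)) {
    cat("final rule set, validation: ")
    print(x$final_eval$validation)
  }
  invisible(x)
}

pipeline_summary <- function(bundle) {
  th <- as.numeric(bundle$thresholds)
  cc <- bundle$config$concepts
  fmt_eval <- function(tag, e) sprintf(
    "%s: accuracy %.3f, fidelity %.3f, sensitivity %.3f, specificity %.3f",
    tag, e$accuracy, e$fidelity, e$sensitivity, e$specificity)
  c(sprintf("run config %s, seed %d", bundle$hash, bundle$config$seed),
    sprintf("CNN: train accuracy %.3f, validation accuracy %.3f",
            bundle$model$train_report$train_accuracy,
            bundle$model$train_report$val_accuracy),
    sprintf("thresholds theta: min %.3f, median %.3f, max %.3f",
            min(th), stats::median(th), max(th)),
    sprintf("concept thresholds: iou_min %.2f, hit_frac %.2f, max_regions %d, percentile %g",
            cc$iou_min, cc$hit_frac, cc$max_regions, cc$percentile),
    sprintf("interpretable kernels: %d of %d",
            length(interpretable_kernels(bundle$concepts)),
            bundle$model$n_kernels),
    fmt_eval("baseline rules (train)", bundle$baseline_eval$train),
    fmt_eval("baseline rules (validation)", bundle$baseline_eval$validation),
    fmt_eval("final rules (train)", bundle$final_eval$train),
    fmt_eval("final rules (validation)", bundle$final_eval$validation),
    sprintf("final rule count: %d", length(bundle$final_rules$rules)))
}

#' Write all pipeline artifacts to a directory
#'
#' @param bundle a `pipeline_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  jsonlite::write_json(c(list(config_hash = bundle$hash),
                         bundle$config),
                       p("config.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  write_boxes(bundle$train_data, p("boxes_train.csv"))
  write_table_csv(bundle$norms_train, p("kernel_norms_train.csv"))
  write_table_csv(bundle$literals_train, p("literals_train.csv"))
  utils::write.csv(data.frame(kernel = kernel_codes(length(bundle$thresholds)),
                              theta = as.numeric(bundle$thresholds)),
                   p("thresholds.csv"), row.names = FALSE)
  write_concepts_csv(bundle$concepts, p("concepts.csv"))
  write_rules_json(bundle$baseline_rules, p("rules_baseline.json"))
  write_rules_json(bundle$final_rules, p("rules_final.json"))
  write_tree_dot(bundle$baseline_tree, p("tree_baseline.dot"))
  write_tree_dot(bundle$final_tree, p("tree_final.dot"))
  evals <- rbind(
    data.frame(rule_set = "baseline", split = "train",
               t(unlist(bundle$baseline_eval$train[c("accuracy", "fidelity",
                                                     "sensitivity", "specificity")]))),
    data.frame(rule_set = "baseline", split = "validation",
               t(unlist(bundle$baseline_eval$validation[c("accuracy", "fidelity",
                                                          "sensitivity", "specificity")]))),
    data.frame(rule_set = "final", split = "train",
               t(unlist(bundle$final_eval$train[c("accuracy", "fidelity",
                                                  "sensitivity", "specificity")]))),
    data.frame(rule_set = "final", split = "validation",
               t(unlist(bundle$final_eval$validation[c("accuracy", "fidelity",
                                                       "sensitivity", "specificity")]))))
  utils::write.csv(evals, p("evaluation.csv"), row.names = FALSE)
  for (nm in names(bundle$ablation))
    write_ablation_csv(bundle$ablation[[nm]],
                       p(sprintf("ablation_%s.csv", nm)))
  if (!is.null(bundle$features))
    utils::write.csv(bundle$features, p("radiomics_features.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$correlations))
    utils::write.csv(bundle$correlations, p("radiomics_correlations.csv"),
                     row.names = FALSE)
  writeLines(pipeline_summary(bundle), p("summary.txt"))
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(config_hash = bundle$hash, seed = bundle$config$seed,
                   files = files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Ask a what-if question of a completed pipeline run
#'
#' Re-induces the rule set under an allow/deny-constrained kernel
#' vocabulary (via [intervene()]) and reports metric deltas against the
#' run's unconstrained rules. Refuses stale bundles whose config hash no
#' longer matches their config.
#'
#' @param bundle a `pipeline_run`.
#' @param allow,deny kernel codes (or ids into the final vocabulary).
#' @param out_dir optional directory for before/after DOT files and the
#'   delta CSV.
#' @return object of class `what_if_report`.
#' @export
what_if <- function(bundle, allow = NULL, deny = NULL, out_dir = NULL) {
  stopifnot(inherits(bundle, "pipeline_run"))
  if (!identical(bundle$hash, config_hash(bundle$config)))
    stopf("stale bundle: config hash mismatch")
  lit <- bundle$final_literals_train
  iv <- intervene(lit, bundle$cnn_pred_train, allow = allow, deny = deny,
                  max_depth = bundle$config$tree$max_depth,
                  min_leaf = bundle$config$tree$min_leaf,
                  labels = bundle$train_data$labels)
  delta <- vapply(c("accuracy", "fidelity", "sensitivity", "specificity"),
                  function(m) iv$constrained_report[[m]] -
                              iv$baseline_report[[m]],
                  numeric(1))
  out <- structure(list(intervention = iv, delta = delta,
                        allow = allow, deny = deny,
                        config_hash = bundle$hash),
                   class = "what_if_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    base_tree <- induce_tree(lit, bundle$cnn_pred_train,
                             max_depth = bundle$config$tree$max_depth,
                             min_leaf = bundle$config$tree$min_leaf)
    cons_tree <- induce_tree(lit, bundle$cnn_pred_train,
                             max_depth = bundle$config$tree$max_depth,
                             min_leaf = bundle$config$tree$min_leaf,
                             allowed_kernels = allow, denied_kernels = deny)
    write_tree_dot(base_tree, file.path(out_dir, "tree_before.dot"))
    write_tree_dot(cons_tree, file.path(out_dir, "tree_after.dot"))
    utils::write.csv(data.frame(metric = names(delta), delta = delta),
                     file.path(out_dir, "what_if_delta.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.what_if_report <- function(x, ...) {
  cat("what_if_report\n")
  print(x$intervention)
  cat("deltas:", paste(sprintf("%s %+0.3f", names(x$delta), x$delta),
                       collapse = ", "), "\n")
  invisible(x)
}
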