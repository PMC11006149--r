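fake_groups <- function(groups, uninterp, K = 16) {
  structure(list(groups = groups, uninterpretable = uninterp,
                 n_kernels = K), class = "kernel_groups")
}

test_that("group construction partitions kernels and rejects overlap", {
  fx <- tiny_trained_model()
  acts <- extract_activations(fx$model, fx$train)
  cm <- assign_concepts(acts, fx$train$boxes, image_size = 64)
  g <- kernel_groups(cm)
  ids <- unlist(g$groups, use.names = FALSE)
  expect_length(intersect(ids, g$uninterpretable), 0)
  expect_setequal(c(ids, g$uninterpretable), 1:16)
  bad <- fake_groups(list(A = 1:2, B = 2:3), 4:16)
  expect_error(cnnrules:::validate_groups(bad), "disjoint")
})

test_that("reference conditions equal the plain model accuracy", {
  fx <- tiny_trained_model()
  g <- fake_groups(list(A = 1:3, B = 4:5), 6:16)
  acts <- extract_activations(fx$model, fx$train)
  inc <- incremental_activation(fx$model, fx$train, g, n_reps = 2,
                                seed = 1, activations = acts)
  plain <- mean(cnn_predict(fx$model, fx$train) == fx$train$labels)
  expect_equal(inc$accuracy[inc$condition == "all_kernels"], plain)
  # muting an empty group equals the reference condition
  g2 <- fake_groups(list(A = 1:3, E = integer(0)), 6:16)
  sm <- single_region_muting(fx$model, fx$train, g2, activations = acts)
  ref <- sm$accuracy[sm$condition == "reference_uninterpretable_muted"]
  expect_equal(sm$accuracy[sm$condition == "muted_E"], ref)
})

test_that("random baselines are seeded and reproducible", {
  fx <- tiny_trained_model()
  g <- fake_groups(list(A = 1:2), 3:16)
  acts <- extract_activations(fx$model, fx$train)
  r1 <- incremental_activation(fx$model, fx$train, g, n_reps = 1,
                               seed = 42, activations = acts)
  r2 <- incremental_activation(fx$model, fx$train, g, n_reps = 1,
                               seed = 42, activations = acts)
  expect_identical(r1$accuracy, r2$accuracy)
  # baselines need enough uninterpretable kernels
  g_big <- fake_groups(list(A = 1:14), 15:16)
  expect_error(incremental_activation(fx$model, fx$train, g_big,
                                      n_reps = 1, seed = 1,
                                      activations = acts), "uninterpretable")
})

test_that("combination ranking is exhaustive, capped and order-invariant", {
  fx <- tiny_trained_model()
  acts <- extract_activations(fx$model, fx$train)
  g <- fake_groups(list(A = 1:2, B = 3:4, C = 5:6, D = 7:8), 9:16)
  r <- combination_ranking(fx$model, fx$train, g, choose = 2, top_k = 10,
                           activations = acts)
  expect_equal(nrow(r), 6)          # choose(4, 2)
  expect_true(all(diff(r$accuracy) <= 0))
  g_rev <- fake_groups(rev(list(A = 1:2, B = 3:4, C = 5:6, D = 7:8)), 9:16)
  r2 <- combination_ranking(fx$model, fx$train, g_rev, choose = 2,
                            top_k = 10, activations = acts)
  expect_equal(r$accuracy[order(r$condition)],
               r2$accuracy[order(r2$condition)])
  # choose = all groups: a single combination, all interpretable active
  r_all <- combination_ranking(fx$model, fx$train, g, choose = 4,
                               activations = acts)
  expect_equal(nrow(r_all), 1)
  keep <- unlist(g$groups, use.names = FALSE)
  acc <- mean(predict_from_activations(
    fx$model, acts, kernel_mask(keep, "activate_only", 16)) ==
    fx$train$labels)
  expect_equal(r_all$accuracy, acc)
  expect_error(combination_ranking(fx$model, fx$train, g, choose = 2,
                                   max_evals = 3, activations = acts),
               "max_evals")
  expect_error(combination_ranking(fx$model, fx$train, g, choose = 9,
                                   activations = acts), "groups")
})

test_that("the random muting curve hits both exact limits", {
  fx <- tiny_trained_model()
  acts <- extract_activations(fx$model, fx$train)
  r <- random_muting_curve(fx$model, fx$train, fractions = c(0, 0.5, 1),
                           n_reps = 3, seed = 2, activations = acts)
  plain <- mean(cnn_predict(fx$model, fx$train) == fx$train$labels)
  expect_equal(r$accuracy[r$condition == "fraction_0.00"], plain)
  # all kernels muted: constant prediction, majority-class accuracy
  maj <- max(table(fx$train$labels)) / length(fx$train$labels)
  expect_equal(r$accuracy[r$condition == "fraction_1.00"], maj)
  expect_equal(sum(r$condition == "fraction_0.50"), 3)
  expect_error(random_muting_curve(fx$model, fx$train,
                                   fractions = c(-0.1),
                                   activations = acts), "fractions")
})

test_that("ablation results export as tidy CSV", {
  fx <- tiny_trained_model()
  acts <- extract_activations(fx$model, fx$train)
  g <- fake_groups(list(A = 1:2), 3:16)
  sm <- single_region_muting(fx$model, fx$train, g, activations = acts)
  path <- tempfile(fileext = ".csv")
  write_ablation_csv(sm, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("experiment", "condition", "replicate", "accuracy",
                     "n_kernels", "pct_kernels"))
})
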