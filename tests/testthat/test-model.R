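test_that("training is deterministic given the seed", {
  cfg <- phantom_config(n_per_class = 12, seed = 5)
  ds <- generate_dataset(cfg)
  m1 <- train_tiny_cnn(ds, seed = 4, epochs = 2, min_val_acc = 0)
  m2 <- train_tiny_cnn(ds, seed = 4, epochs = 2, min_val_acc = 0)
  expect_identical(m1$params, m2$params)
  expect_identical(cnn_predict(m1, ds), cnn_predict(m2, ds))
  m3 <- train_tiny_cnn(ds, seed = 5, epochs = 2, min_val_acc = 0)
  expect_false(identical(m1$params$Wl, m3$params$Wl))
})

test_that("activation extraction has the contracted shape and is pure", {
  fx <- tiny_trained_model()
  acts <- extract_activations(fx$model, fx$train)
  d <- dim(acts$activations)
  expect_equal(d, c(80, 16, 16, 16))
  expect_true(all(is.finite(acts$activations)))
  expect_true(all(acts$activations >= 0))   # post-ReLU layer
  acts2 <- extract_activations(fx$model, fx$train)
  expect_identical(acts$activations, acts2$activations)
  wrong <- array(0, c(1, 32, 32))
  expect_error(extract_activations(fx$model, wrong), "expects")
})

test_that("a constant-zero image yields all-zero maps in a bias-free model", {
  fx <- tiny_trained_model()
  model <- fx$model
  model$params$b1[] <- 0
  model$params$b2[] <- 0
  model$params$b3[] <- 0
  acts <- extract_activations(model, matrix(0, 64, 64))
  expect_true(all(acts$activations == 0))
})

test_that("masking identities hold exactly", {
  fx <- tiny_trained_model()
  model <- fx$model
  ds <- fx$train
  plain <- cnn_predict(model, ds)

  # empty mute mask reproduces the unmasked predictions
  empty <- kernel_mask(integer(0), "mute", 16)
  expect_identical(predict_masked(model, ds, empty), plain)

  # muting all kernels forces a constant prediction
  all_mute <- kernel_mask(1:16, "mute", 16)
  p <- predict_masked(model, ds, all_mute)
  expect_equal(length(unique(p)), 1)

  # activate_only(S) == mute(complement of S) on random subsets
  set.seed(17)
  for (i in 1:20) {
    S <- sample(16, sample(0:16, 1))
    a <- predict_masked(model, ds, kernel_mask(S, "activate_only", 16))
    b <- predict_masked(model, ds, kernel_mask(setdiff(1:16, S), "mute", 16))
    expect_identical(a, b)
  }

  # masking is stateless: interleaved calls do not contaminate each other
  expect_identical(cnn_predict(model, ds), plain)
  expect_error(kernel_mask(c(1, 99), "mute", 16), "1..16")
})

test_that("the h() path on stored activations matches the full forward pass", {
  fx <- tiny_trained_model()
  acts <- extract_activations(fx$model, fx$train)
  expect_identical(predict_from_activations(fx$model, acts),
                   cnn_predict(fx$model, fx$train))
  mask <- kernel_mask(c(2, 5), "mute", 16)
  expect_identical(predict_from_activations(fx$model, acts, mask),
                   predict_masked(fx$model, fx$train, mask))
})

test_that("models survive a checkpoint round trip", {
  fx <- tiny_trained_model()
  path <- tempfile(fileext = ".rds")
  save_model(fx$model, path)
  back <- load_model(path)
  expect_identical(back$params, fx$model$params)
  expect_identical(cnn_predict(back, fx$val), cnn_predict(fx$model, fx$val))
})

test_that("non-converging training raises a diagnostic error", {
  cfg <- phantom_config(n_per_class = 10, seed = 2,
                        signal_amp_factor = 1, fill_mean = 0.45)
  ds <- generate_dataset(cfg)   # no class signal at all
  expect_error(train_tiny_cnn(ds, seed = 1, epochs = 1, min_val_acc = 0.9),
               "validation accuracy")
  unbalanced <- generate_dataset(cfg)
  unbalanced$labels[1] <- 1L
  expect_error(train_tiny_cnn(unbalanced, seed = 1, epochs = 1),
               "balanced")
})

test_that("activation export writes a binary container with an index", {
  fx <- tiny_trained_model()
  acts <- extract_activations(fx$model, fx$val)
  prefix <- tempfile()
  export_activations(acts, prefix)
  idx <- utils::read.csv(paste0(prefix, "_index.csv"))
  expect_equal(nrow(idx), 30 * 16)
  con <- file(paste0(prefix, ".bin"), "rb")
  vals <- readBin(con, "double", n = 30 * 16 * 16 * 16)
  close(con)
  expect_equal(length(vals), 30 * 16 * 16 * 16)
  expect_equal(vals[1], acts$activations[1, 1, 1, 1])
})
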