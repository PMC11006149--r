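crop_from_levels <- function(lv, n_gray = max(lv)) {
  cnnrules:::as_region_crop(as.matrix(lv), n_gray = n_gray)
}

test_that("GLCM joint entropy matches hand-computed cases", {
  # constant crop: a single co-occurrence pair, zero bits
  expect_equal(glcm_joint_entropy(crop_from_levels(matrix(1, 3, 3))), 0)
  # 2x2 checkerboard, horizontal angle: p = {(1,2): .5, (2,1): .5} -> 1 bit
  cb <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_equal(glcm_joint_entropy(crop_from_levels(cb, 2), "horizontal"), 1)
  expect_equal(glcm_joint_entropy(crop_from_levels(cb, 2), "vertical"), 1)
  # its diagonals pair equal levels only: zero bits
  expect_equal(glcm_joint_entropy(crop_from_levels(cb, 2), "diag_down"), 0)
})

test_that("GLCM joint entropy matches brute-force pair enumeration", {
  set.seed(5)
  for (i in 1:25) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    lv <- matrix(sample(1:4, nr * nc, replace = TRUE), nr, nc)
    got <- glcm_joint_entropy(crop_from_levels(lv, 4))
    expect_equal(got, oracle_glcm_entropy(lv), tolerance = 1e-9)
  }
})

test_that("joint entropy is bounded by the uniform joint distribution", {
  set.seed(8)
  for (i in 1:10) {
    ng <- sample(2:6, 1)
    lv <- matrix(sample(seq_len(ng), 64, replace = TRUE), 8, 8)
    expect_lte(glcm_joint_entropy(crop_from_levels(lv, ng)),
               2 * log2(ng) + 1e-12)
  }
})

test_that("GLRLM non-uniformities match hand-enumerated runs", {
  # constant 1x4 row: one run of length 4 -> GLN = RLN = 1
  nu <- glrlm_nonuniformities(crop_from_levels(matrix(1, 1, 4)),
                              "horizontal")
  expect_equal(unname(nu), c(1, 1))
  # row [1,1,2,2]: runs {(1,2),(2,2)} -> GLN = 1, RLN = 2
  nu2 <- glrlm_nonuniformities(crop_from_levels(matrix(c(1, 1, 2, 2), 1, 4),
                                                2), "horizontal")
  expect_equal(unname(nu2), c(1, 2))
})

test_that("GLRLM features match brute-force run enumeration", {
  set.seed(6)
  for (i in 1:25) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    lv <- matrix(sample(1:3, nr * nc, replace = TRUE), nr, nc)
    got <- glrlm_nonuniformities(crop_from_levels(lv, 3))
    want <- oracle_glrlm_nonuniformities(lv)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("first-order features follow their definitions", {
  const <- cnnrules:::as_region_crop(matrix(1, 2, 2), values = matrix(0.4, 2, 2))
  fo <- first_order(const)
  expect_equal(unname(fo), c(0, 0.4))
  two <- cnnrules:::as_region_crop(matrix(1, 1, 2), values = matrix(c(0, 2), 1, 2))
  fo2 <- first_order(two)
  expect_equal(unname(fo2), c(1, sqrt(2)))
  # homogeneity under intensity scaling
  sc <- cnnrules:::as_region_crop(matrix(1, 1, 2), values = matrix(c(0, 2) * 3, 1, 2))
  expect_equal(unname(first_order(sc)), unname(fo2) * 3)
})

test_that("discretization maps crops into 1..n_gray", {
  img <- matrix(runif(100), 10, 10)
  crop <- region_crop(img, c(1, 1, 9, 9), n_gray = 8)
  expect_true(all(crop$levels >= 1 & crop$levels <= 8))
  expect_equal(dim(crop$values), c(8, 8))
  flat <- region_crop(matrix(0.5, 4, 4), c(0, 0, 4, 4))
  expect_true(all(flat$levels == 1))
  expect_error(region_crop(img, c(3, 3, 3, 6)))
})

test_that("feature tables cover every image, region and feature", {
  cfg <- phantom_config(n_per_class = 2, seed = 9)
  ds <- generate_dataset(cfg)
  ft <- feature_table(ds, regions = c("UM", "CS"))
  expect_equal(nrow(ft), 4 * 2 * 5)
  expect_true(all(is.finite(ft$value)))
  expect_true(all(ft$value[ft$feature == "GLCM_JointEntropy"] >= 0))
})

test_that("norm-feature correlations report exact degenerate cases", {
  norms <- kernel_norms(matrix(seq(1, 40), 20, 2))
  feats <- data.frame(image_id = 1:20, region = "UM",
                      feature = "GLCM_JointEntropy",
                      value = 2 * seq_len(20) + 1)
  r <- correlate_norms(norms, feats, kernel = 1, region = "UM")
  expect_equal(r$r, 1)
  expect_equal(r$slope, 2)
  feats$value <- -seq_len(20)
  expect_equal(correlate_norms(norms, feats, 1, "UM")$r, -1)
  feats$value <- 5
  expect_true(is.na(correlate_norms(norms, feats, 1, "UM")$r))
  expect_error(correlate_norms(norms, feats[1:2, ], 1, "UM"), "3")
})
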