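test_that("iou matches hand counts and a pixel-counting oracle", {
  expect_equal(iou(c(0, 0, 4, 4), c(0, 0, 4, 4)), 1)
  expect_equal(iou(c(0, 0, 4, 4), c(10, 10, 12, 12)), 0)
  expect_equal(iou(c(0, 0, 4, 4), c(2, 0, 6, 4)), 1 / 3)  # 8 / 24 pixels
  set.seed(13)
  for (i in 1:1000) {
    a <- sort(sample(0:32, 2))
    while (a[1] == a[2]) a <- sort(sample(0:32, 2))
    ay <- sort(sample(0:32, 2))
    while (ay[1] == ay[2]) ay <- sort(sample(0:32, 2))
    b <- sort(sample(0:32, 2))
    while (b[1] == b[2]) b <- sort(sample(0:32, 2))
    by <- sort(sample(0:32, 2))
    while (by[1] == by[2]) by <- sort(sample(0:32, 2))
    bx_a <- c(a[1], ay[1], a[2], ay[2])
    bx_b <- c(b[1], by[1], b[2], by[2])
    got <- iou(bx_a, bx_b)
    expect_equal(got, oracle_iou_pixels(bx_a, bx_b, 32))
    expect_equal(got, iou(bx_b, bx_a))   # symmetry
    expect_gte(got, 0)
    expect_lte(got, 1)
  }
})

test_that("activation boxes localize hot map regions", {
  # single nonzero cell: nearest-neighbour upsampling gives its footprint
  m <- matrix(0, 4, 4)
  m[2, 3] <- 1
  box <- activation_box(m, 64, interp = "nearest")
  expect_equal(as.numeric(box), c(32, 16, 48, 32))
  # all-zero map is silent
  expect_null(activation_box(matrix(0, 4, 4), 64))
  # a constant positive map covers the whole image (a diffuse kernel)
  expect_equal(as.numeric(activation_box(matrix(2, 4, 4), 64)),
               c(0, 0, 64, 64))
  # 2x2 hot corner of a 4x4 map, bilinear: box confined to that quadrant
  m2 <- matrix(0, 4, 4)
  m2[1:2, 1:2] <- 1
  b2 <- activation_box(m2, 64, percentile = 90)
  expect_lte(unname(b2["x1"]), 40)
  expect_lte(unname(b2["y1"]), 40)
  expect_gte(iou(b2, c(0, 0, 32, 32)), 0.3)
})

synthetic_acts <- function(boxes_fn, n = 10, k = 2, ms = 16, size = 64) {
  arr <- array(0, c(n, k, ms, ms))
  for (i in seq_len(n)) for (kk in seq_len(k)) {
    b <- boxes_fn(i, kk)
    if (!is.null(b)) {
      cells <- round(b / (size / ms))
      arr[i, kk, (cells[2] + 1):cells[4], (cells[1] + 1):cells[3]] <- 1
    }
  }
  structure(list(activations = arr, image_ids = seq_len(n),
                 layer_id = "synthetic", map_size = ms),
            class = "activation_set")
}

test_that("concept assignment follows the stated hit-rate thresholds", {
  regions <- data.frame(region = c("A", "B"),
                        x0 = c(8, 40), y0 = c(8, 40),
                        x1 = c(28, 60), y1 = c(28, 60))
  # kernel 1 always boxes region A exactly; kernel 2 stays silent
  acts <- synthetic_acts(function(i, k)
    if (k == 1) c(8, 8, 28, 28) else NULL)
  cm <- assign_concepts(acts, regions, interp = "nearest", image_size = 64)
  expect_identical(cm$assignment$region[1], "A")
  expect_equal(unname(cm$hit_rates[1, "A"]), 1)
  expect_identical(cm$assignment$region[2], "UNINTERPRETABLE")
  expect_equal(sum(cm$hit_rates[2, ]), 0)
})

test_that("kernels hitting too many overlapping regions are uninterpretable", {
  regions <- data.frame(region = c("A", "B", "C"),
                        x0 = c(8, 8, 9), y0 = c(8, 9, 8),
                        x1 = c(28, 28, 29), y1 = c(28, 29, 28))
  acts <- synthetic_acts(function(i, k) c(8, 8, 28, 28), k = 1)
  cm3 <- assign_concepts(acts, regions, interp = "nearest",
                         max_regions = 2, image_size = 64)
  expect_identical(cm3$assignment$region[1], "UNINTERPRETABLE")
  expect_true(all(cm3$hit_rates[1, ] > 0.7))
  # with max_regions = 3 the max-rate region (exact match, name order) wins
  cm4 <- assign_concepts(acts, regions, interp = "nearest",
                         max_regions = 3, image_size = 64)
  expect_identical(cm4$assignment$region[1], "A")
})

test_that("raising iou_min never raises a hit rate", {
  set.seed(31)
  regions <- phantom_regions(64)
  arr <- array(stats::runif(8 * 3 * 16 * 16), c(8, 3, 16, 16))
  acts <- structure(list(activations = arr, image_ids = 1:8,
                         layer_id = "t", map_size = 16),
                    class = "activation_set")
  lo <- assign_concepts(acts, regions, iou_min = 0.3, image_size = 64)
  hi <- assign_concepts(acts, regions, iou_min = 0.6, image_size = 64)
  expect_true(all(hi$hit_rates <= lo$hit_rates))
})

test_that("missing boxes raise an error naming the images", {
  acts <- synthetic_acts(function(i, k) c(8, 8, 28, 28), n = 5, k = 1)
  boxes <- rep(list(data.frame(region = "A", x0 = 8, y0 = 8,
                               x1 = 28, y1 = 28)), 3)
  expect_error(assign_concepts(acts, boxes, image_size = 64), "image")
})

test_that("filtering keeps only interpretable kernel columns", {
  regions <- data.frame(region = "A", x0 = 8, y0 = 8, x1 = 28, y1 = 28)
  acts <- synthetic_acts(function(i, k)
    if (k == 1) c(8, 8, 28, 28) else NULL, k = 4)
  cm <- assign_concepts(acts, regions, interp = "nearest", image_size = 64)
  lit <- cnnrules:::as_literal_table(random_literal_matrix(10, 4, 1))
  flt <- filter_interpretable(lit, cm)
  expect_equal(ncol(flt$literals), 1)
  expect_identical(colnames(flt$literals), "AA")
  tree <- induce_tree(flt, rep(c(0L, 1L), 5))
  expect_true(all(cnnrules:::tree_kernels_used(tree$root) %in% 1))

  # all interpretable: identity
  cm$assignment$region <- "A"
  flt2 <- filter_interpretable(lit, cm)
  expect_equal(flt2$literals, lit$literals)
  cm$assignment$region <- "UNINTERPRETABLE"
  expect_error(filter_interpretable(lit, cm), "interpretable")
})

test_that("concept maps export to CSV", {
  regions <- data.frame(region = "A", x0 = 8, y0 = 8, x1 = 28, y1 = 28)
  acts <- synthetic_acts(function(i, k) c(8, 8, 28, 28), k = 2)
  cm <- assign_concepts(acts, regions, interp = "nearest", image_size = 64)
  path <- tempfile(fileext = ".csv")
  write_concepts_csv(cm, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 2)
  expect_true("A" %in% names(back))
})
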