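#' Default phantom region layout
#'
#' A 3x3 grid of non-overlapping square boxes named after the nine
#' anatomical regions used for frontal chest X-ray concept assignment:
#' Trachea (T), Upper Mediastinum (UM), Cardiac Silhouette (CS), Left/Right
#' Clavicle (LC/RC), Left/Right Hilar (LH/RH), and Left/Right Costophrenic
#' Angle (LCA/RCA). The grid is laid out loosely anatomically (clavicles and
#' trachea on top, hilar regions and mediastinum in the middle, costophrenic
#' angles and cardiac silhouette at the bottom). Coordinates are 0-based,
#' half-open pixel bounds.
#'
#' @param image_size side length in pixels of the square image.
#' @return data.frame with columns `region`, `x0`, `y0`, `x1`, `y1`.
#' @export
phantom_regions <- function(image_size = 64) {
  stopifnot(image_size >= 12)
  names3 <- matrix(c(
    "LC",  "T",  "RC",
    "LH",  "UM", "RH",
    "LCA", "CS", "RCA"
  ), nrow = 3, byrow = TRUE)
  margin <- max(1L, round(image_size / 32))
  cell <- (image_size - 2L * margin) %/% 3L
  out <- vector("list", 9L)
  idx <- 1L
  for (r in 1:3) for (cc in 1:3) {
    x0 <- margin + (cc - 1L) * cell
    y0 <- margin + (r - 1L) * cell
    out[[idx]] <- data.frame(
      region = names3[r, cc],
      x0 = x0, y0 = y0, x1 = x0 + cell, y1 = y0 + cell,
      stringsAsFactors = FALSE
    )
    idx <- idx + 1L
  }
  do.call(rbind, out)
}

#' Phantom generator configuration
#'
#' Defines a balanced two-class phantom study: square grayscale images on
#' \[0,1\] containing named rectangular regions. Every region carries a
#' structured sinusoidal texture with a region-specific orientation and
#' period (a persistent "anatomical" signature). In the positive class
#' (label 1, effusion-like) the `signal_regions` are homogenized: structure
#' amplitude is damped, the mean intensity is raised, and the pixel noise
#' can optionally be reduced — emulating the texture obscuring that fluid
#' causes in a radiograph. All other regions are class-independent.
#'
#' @param image_size square image side in pixels.
#' @param regions data.frame of region boxes as from [phantom_regions()].
#' @param signal_regions names of regions carrying class-dependent texture.
#' @param n_per_class images per class.
#' @param seed integer seed; together with the config it fully determines
#'   the generated dataset.
#' @param structure_amp amplitude of the sinusoidal texture in signal
#'   regions (intensity units in \[0,1\]).
#' @param decoy_structure_amp amplitude of the class-independent texture in
#'   non-signal regions; kept below `structure_amp` so signal-region
#'   detectors stay dominant even under positive-class damping.
#' @param noise_sd pixel noise sd inside structured regions.
#' @param homog_noise_sd pixel noise sd inside homogenized signal regions
#'   (positive class).
#' @param signal_amp_factor multiplier applied to `structure_amp` in signal
#'   regions of positive-class images (0 removes the structure entirely).
#' @param base_mean mean intensity of structured regions.
#' @param fill_mean mean intensity of homogenized signal regions
#'   (positive class); raised relative to `base_mean`.
#' @param bg_mean,bg_noise_sd background mean and noise sd.
#' @param region_gain_jitter per-(image, region) multiplicative texture
#'   amplitude jitter (uniform in `1 +/- region_gain_jitter`); emulates
#'   local contrast variation between acquisitions. 0 disables it.
#' @param region_mean_jitter_sd per-(image, region) additive mean
#'   intensity jitter sd.
#' @param gain_range per-image multiplicative exposure range (uniform);
#'   `c(1, 1)` (the default) disables it.
#' @param offset_sd per-image additive intensity offset sd (default 0).
#' @param jitter integer; per-image uniform box jitter in pixels (0 = off).
#'   Jitter perturbs only the *reported* boxes (emulating detection noise),
#'   clipped to the image bounds; textures stay at the canonical layout.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 64,
                           regions = phantom_regions(image_size),
                           signal_regions = c("UM", "CS"),
                           n_per_class = 200,
                           seed = 1L,
                           structure_amp = 0.32,
                           decoy_structure_amp = 0.10,
                           noise_sd = 0.03,
                           homog_noise_sd = 0.03,
                           signal_amp_factor = 0.6,
                           base_mean = 0.45,
                           fill_mean = 0.65,
                           bg_mean = 0.20,
                           bg_noise_sd = 0.02,
                           region_gain_jitter = 0.15,
                           region_mean_jitter_sd = 0.02,
                           gain_range = c(1, 1),
                           offset_sd = 0,
                           jitter = 0L) {
  stopifnot(is.data.frame(regions),
            all(c("region", "x0", "y0", "x1", "y1") %in% names(regions)))
  if (anyDuplicated(regions$region)) stopf("region names must be unique")
  if (!all(signal_regions %in% regions$region))
    stopf("signal_regions must be a subset of region names")
  if (n_per_class < 1) stopf("n_per_class must be >= 1")
  with(regions, {
    if (any(x0 < 0 | y0 < 0 | x1 > image_size | y1 > image_size))
      stopf("region boxes must lie within the image")
    if (any(x0 >= x1 | y0 >= y1)) stopf("region boxes must be non-empty")
  })
  # overlapping signal regions would make the class signal ambiguous
  sig <- regions[regions$region %in% signal_regions, , drop = FALSE]
  if (nrow(sig) > 1) {
    for (i in seq_len(nrow(sig) - 1)) for (j in (i + 1):nrow(sig)) {
      ix <- min(sig$x1[i], sig$x1[j]) - max(sig$x0[i], sig$x0[j])
      iy <- min(sig$y1[i], sig$y1[j]) - max(sig$y0[i], sig$y0[j])
      if (ix > 0 && iy > 0)
        stopf("signal regions '%s' and '%s' overlap", sig$region[i], sig$region[j])
    }
  }
  # persistent per-region texture signature: orientation and period vary
  # by region index so each region has a recognizably distinct texture
  nr <- nrow(regions)
  # signal regions carry fine, axis-aligned gratings (short period and
  # strong 3x3 conv coupling); decoys carry coarser oblique gratings so
  # kernels tuned to a signal region stay spatially selective in both
  # classes while every region keeps a distinctive persistent signature
  is_sig <- regions$region %in% signal_regions
  n_sig <- sum(is_sig); n_dec <- sum(!is_sig)
  theta <- period <- numeric(nr)
  # oblique orientations (axis-aligned fine gratings do not survive 2x2
  # max-pooling well); signal regions additionally separated in period
  sig_theta <- (c(80, 145, 25, 110, 55, 170) * pi / 180)
  theta[is_sig] <- sig_theta[(seq_len(n_sig) - 1) %% 6 + 1]
  period[is_sig] <- 3
  ang_dist <- function(a, b) {
    d <- abs(a - b) %% pi
    pmin(d, pi - d)
  }
  cand <- seq(0, 175, by = 5) * pi / 180
  far <- cand[vapply(cand, function(a)
    n_sig == 0 || all(ang_dist(a, theta[is_sig]) > 15 * pi / 180),
    logical(1))]
  theta[!is_sig] <- far[round(seq(1, length(far), length.out = n_dec))]
  period[!is_sig] <- 5 + (seq_len(n_dec) - 1) %% 2
  signature <- data.frame(
    region = regions$region,
    theta  = theta,
    period = period,
    stringsAsFactors = FALSE
  )
  structure(list(
    image_size = as.integer(image_size), regions = regions,
    signal_regions = signal_regions, n_per_class = as.integer(n_per_class),
    seed = as.integer(seed), structure_amp = structure_amp,
    decoy_structure_amp = decoy_structure_amp,
    noise_sd = noise_sd, homog_noise_sd = homog_noise_sd,
    signal_amp_factor = signal_amp_factor, base_mean = base_mean,
    fill_mean = fill_mean, bg_mean = bg_mean, bg_noise_sd = bg_noise_sd,
    region_gain_jitter = region_gain_jitter,
    region_mean_jitter_sd = region_mean_jitter_sd,
    gain_range = as.numeric(gain_range), offset_sd = offset_sd,
    jitter = as.integer(jitter), signature = signature
  ), class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("phantom_config: %dx%d, %d regions (%s signal), %d per class, seed %d\n",
              x$image_size, x$image_size, nrow(x$regions),
              paste(x$signal_regions, collapse = "/"), x$n_per_class, x$seed))
  invisible(x)
}

# textured patch for one region; draws from the current RNG stream
region_patch <- function(config, region, label) {
  box <- config$regions[config$regions$region == region, ]
  sg <- config$signature[config$signature$region == region, ]
  h <- box$y1 - box$y0
  w <- box$x1 - box$x0
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  phase <- stats::runif(1, 0, 2 * pi)
  is_signal <- region %in% config$signal_regions
  if (is_signal && label == 1L) {
    amp <- config$structure_amp * config$signal_amp_factor
    mu <- config$fill_mean
    sd <- config$homog_noise_sd
  } else if (is_signal) {
    amp <- config$structure_amp
    mu <- config$base_mean
    sd <- config$noise_sd
  } else {
    amp <- config$decoy_structure_amp
    mu <- config$base_mean
    sd <- config$noise_sd
  }
  # per-(image, region) contrast and brightness jitter, class-independent
  if (config$region_gain_jitter > 0)
    amp <- amp * stats::runif(1, 1 - config$region_gain_jitter,
                              1 + config$region_gain_jitter)
  if (config$region_mean_jitter_sd > 0)
    mu <- mu + stats::rnorm(1, 0, config$region_mean_jitter_sd)
  grating <- amp * sin(2 * pi * (cos(sg$theta) * cc + sin(sg$theta) * rr) / sg$period + phase)
  mu + grating + matrix(stats::rnorm(h * w, 0, sd), h, w)
}

#' Generate a single phantom image
#'
#' Draws one image and its region boxes from the configured layout. The
#' background is low-amplitude noise; every region receives its signature
#' texture, with signal regions homogenized when `label == 1`.
#'
#' @param config a [phantom_config()].
#' @param label 0 (healthy-like, structured signal regions) or 1
#'   (effusion-like, homogenized signal regions).
#' @param seed optional integer; when given, seeds the RNG so repeated calls
#'   are identical. When `NULL` the current RNG stream is used (this is how
#'   [generate_dataset()] drives it).
#' @return list with `image` (matrix, rows = y) and `boxes` (data.frame).
#' @export
generate_image <- function(config, label, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  label <- check_binary(label, "label")
  if (!is.null(seed)) set.seed(seed)
  s <- config$image_size
  img <- matrix(config$bg_mean + stats::rnorm(s * s, 0, config$bg_noise_sd), s, s)
  for (region in config$regions$region) {
    box <- config$regions[config$regions$region == region, ]
    img[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1] <-
      region_patch(config, region, label)
  }
  # per-image exposure variation (class-independent)
  if (config$gain_range[1] != 1 || config$gain_range[2] != 1)
    img <- img * stats::runif(1, config$gain_range[1], config$gain_range[2])
  if (config$offset_sd > 0)
    img <- img + stats::rnorm(1, 0, config$offset_sd)
  img <- pmin(pmax(img, 0), 1)
  boxes <- config$regions
  if (config$jitter > 0) {
    j <- config$jitter
    for (i in seq_len(nrow(boxes))) {
      dx <- sample(seq(-j, j), 1)
      dy <- sample(seq(-j, j), 1)
      boxes$x0[i] <- max(0L, min(s - 1L, boxes$x0[i] + dx))
      boxes$x1[i] <- max(boxes$x0[i] + 1L, min(s, boxes$x1[i] + dx))
      boxes$y0[i] <- max(0L, min(s - 1L, boxes$y0[i] + dy))
      boxes$y1[i] <- max(boxes$y0[i] + 1L, min(s, boxes$y1[i] + dy))
    }
  }
  list(image = img, boxes = boxes)
}

#' Generate a balanced phantom dataset
#'
#' Produces `2 * n_per_class` images with labels interleaved 0,1,0,1,...
#' deterministically. The same config and seed reproduce the dataset
#' bit-for-bit.
#'
#' @param config a [phantom_config()].
#' @return object of class `phantom_dataset`: list with `images`
#'   (array `n x H x W`), `labels` (integer vector), `boxes` (list of
#'   per-image box data.frames), `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  n <- 2L * config$n_per_class
  s <- config$image_size
  images <- array(0, c(n, s, s))
  labels <- rep(c(0L, 1L), config$n_per_class)
  boxes <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_image(config, labels[i], seed = NULL)
    images[i, , ] <- g$image
    boxes[[i]] <- g$boxes
  }
  structure(list(images = images, labels = labels, boxes = boxes,
                 config = config),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("phantom_dataset: %d images (%dx%d), labels %d/%d, %d regions\n",
              length(x$labels), dim(x$images)[2], dim(x$images)[3],
              sum(x$labels == 0), sum(x$labels == 1), nrow(x$config$regions)))
  invisible(x)
}

#' Write region boxes to CSV
#'
#' One row per (image, region): columns `image_id`, `region`, `x0`, `y0`,
#' `x1`, `y1` with 0-based half-open pixel coordinates. The same dialect is
#' read back by [read_boxes()] and accepted wherever per-image boxes are
#' consumed (e.g. boxes produced by an external detection model).
#'
#' @param dataset a `phantom_dataset`, or a list of per-image box
#'   data.frames.
#' @param path output CSV path.
#' @export
write_boxes <- function(dataset, path) {
  boxes <- if (inherits(dataset, "phantom_dataset")) dataset$boxes else dataset
  rows <- lapply(seq_along(boxes), function(i)
    cbind(image_id = i, boxes[[i]][, c("region", "x0", "y0", "x1", "y1")]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read region boxes from CSV
#'
#' @param path CSV path in the dialect of [write_boxes()].
#' @return list of per-image box data.frames, indexed by `image_id`.
#' @export
read_boxes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "region", "x0", "y0", "x1", "y1")
  if (!all(need %in% names(df))) stopf("box CSV must have columns %s",
                                       paste(need, collapse = ", "))
  lapply(split(df, df$image_id), function(d) d[, -1, drop = FALSE])
}

#' Write phantom images as 8-bit grayscale PNGs
#'
#' @param dataset a `phantom_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_phantom_png <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$labels)) {
    png::writePNG(dataset$images[i, , ],
                  file.path(dir, sprintf("img_%04d_label%d.png", i,
                                         dataset$labels[i])))
  }
  invisible(dir)
}
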