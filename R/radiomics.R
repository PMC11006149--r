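# Texture features on region crops: GLCM joint entropy, GLRLM gray-level
# and run-length non-uniformities, first-order MAD and RMS, and their
# correlation with kernel norms. Gray-level discretization is per-crop
# min-max into a fixed number of bins; first-order features use the raw
# intensities.

#' Crop a region from an image and discretize it
#'
#' @param image intensity matrix (rows = y) on \[0, 1\].
#' @param box a [region_box()] or numeric `c(x0, y0, x1, y1)` (0-based,
#'   half-open).
#' @param n_gray number of gray levels for the discretized crop.
#' @return object of class `region_crop`: list with `values` (raw
#'   intensities), `levels` (integers 1..n_gray; a constant crop maps to
#'   level 1), `n_gray`.
#' @export
region_crop <- function(image, box, n_gray = 32L) {
  b <- as.numeric(box)
  stopifnot(b[1] < b[3], b[2] < b[4], n_gray >= 2)
  vals <- image[(b[2] + 1):b[4], (b[1] + 1):b[3], drop = FALSE]
  rng <- range(vals)
  lv <- if (rng[1] == rng[2]) matrix(1L, nrow(vals), ncol(vals))
        else pmin(floor((vals - rng[1]) / (rng[2] - rng[1]) * n_gray) + 1L,
                  n_gray)
  structure(list(values = vals, levels = lv, n_gray = as.integer(n_gray)),
            class = "region_crop")
}

# build a region_crop from an existing level matrix (fixtures, oracles)
as_region_crop <- function(levels, values = NULL, n_gray = max(levels)) {
  levels <- as.matrix(levels)
  stopifnot(all(levels >= 1), all(levels == floor(levels)))
  structure(list(values = values %||% (levels / n_gray),
                 levels = levels, n_gray = as.integer(n_gray)),
            class = "region_crop")
}

glcm_angles <- list(horizontal = c(0L, 1L), diag_up = c(-1L, 1L),
                    vertical = c(-1L, 0L), diag_down = c(-1L, -1L))

# co-occurrence counts for one (drow, dcol) offset, symmetric
glcm_counts <- function(lv, off, n_gray) {
  nr <- nrow(lv); nc <- ncol(lv)
  r0 <- max(1, 1 - off[1]):min(nr, nr - off[1])
  c0 <- max(1, 1 - off[2]):min(nc, nc - off[2])
  a <- lv[r0, c0, drop = FALSE]
  b <- lv[r0 + off[1], c0 + off[2], drop = FALSE]
  tab <- tabulate((as.vector(a) - 1L) * n_gray + as.vector(b),
                  nbins = n_gray * n_gray)
  cm <- matrix(tab, n_gray, n_gray)
  cm + t(cm)   # symmetric co-occurrence counts
}

#' GLCM joint entropy of a region crop
#'
#' Builds the symmetric gray-level co-occurrence matrix at distance 1 for
#' each requested angle, normalizes it to probabilities and computes the
#' Shannon entropy (base 2, with 0 log 0 = 0), averaged over angles. Low
#' values indicate homogeneous texture.
#'
#' @param crop a [region_crop()].
#' @param angles subset of `c("horizontal", "diag_up", "vertical",
#'   "diag_down")` (0/45/90/135 degrees); default all four.
#' @return joint entropy in bits.
#' @export
glcm_joint_entropy <- function(crop, angles = names(glcm_angles)) {
  stopifnot(inherits(crop, "region_crop"))
  if (nrow(crop$levels) < 2 || ncol(crop$levels) < 2)
    stopf("crop must be at least 2x2 for co-occurrence features")
  angles <- match.arg(angles, names(glcm_angles), several.ok = TRUE)
  ent <- vapply(angles, function(a) {
    cm <- glcm_counts(crop$levels, glcm_angles[[a]], crop$n_gray)
    p <- cm / sum(cm)
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  mean(ent)
}

glrlm_directions <- list(horizontal = "h", vertical = "v",
                         diag_down = "d1", diag_up = "d2")

# run-length matrix (rows = gray level, cols = run length) for a direction
glrlm_matrix <- function(lv, dir, n_gray) {
  nr <- nrow(lv); nc <- ncol(lv)
  lines <- switch(dir,
    h  = lapply(seq_len(nr), function(i) lv[i, ]),
    v  = lapply(seq_len(nc), function(j) lv[, j]),
    d1 = lapply(seq(-(nr - 1), nc - 1), function(d)
           lv[row(lv) - col(lv) == -d]),         # top-left -> bottom-right
    d2 = lapply(seq(2, nr + nc), function(s)
           lv[row(lv) + col(lv) == s]))          # bottom-left -> top-right
  maxlen <- max(nr, nc)
  P <- matrix(0, n_gray, maxlen)
  for (ln in lines) {
    if (!length(ln)) next
    r <- rle(as.vector(ln))
    for (j in seq_along(r$lengths))
      P[r$values[j], r$lengths[j]] <- P[r$values[j], r$lengths[j]] + 1
  }
  P
}

#' GLRLM non-uniformities of a region crop
#'
#' From the run-length matrix P(i, j) (gray level i, run length j) of each
#' direction: Gray Level Non-Uniformity = sum_i (sum_j P)^2 / N_r and Run
#' Length Non-Uniformity = sum_j (sum_i P)^2 / N_r, where N_r is the total
#' number of runs; both averaged over directions. High values indicate
#' texture dominated by few gray levels / few run lengths.
#'
#' @param crop a [region_crop()].
#' @param directions subset of `c("horizontal", "vertical", "diag_down",
#'   "diag_up")`; default all four.
#' @return named numeric `c(gln, rln)`.
#' @export
glrlm_nonuniformities <- function(crop, directions = names(glrlm_directions)) {
  stopifnot(inherits(crop, "region_crop"))
  if (length(crop$levels) < 2)
    stopf("crop must have at least 2 pixels for run-length features")
  directions <- match.arg(directions, names(glrlm_directions),
                          several.ok = TRUE)
  vals <- vapply(directions, function(d) {
    P <- glrlm_matrix(crop$levels, glrlm_directions[[d]], crop$n_gray)
    nr_runs <- sum(P)
    c(sum(rowSums(P)^2) / nr_runs, sum(colSums(P)^2) / nr_runs)
  }, numeric(2))
  c(gln = mean(vals[1, ]), rln = mean(vals[2, ]))
}

#' First-order intensity features of a region crop
#'
#' Computed on raw (non-discretized) intensities: mean absolute deviation
#' `mean(|x - mean(x)|)` and root mean square `sqrt(mean(x^2))`.
#'
#' @param crop a [region_crop()].
#' @return named numeric `c(mad, rms)`.
#' @export
first_order <- function(crop) {
  stopifnot(inherits(crop, "region_crop"))
  x <- as.vector(crop$values)
  c(mad = mean(abs(x - mean(x))), rms = sqrt(mean(x^2)))
}

radiomics_feature_ids <- c("GLCM_JointEntropy", "GLRLM_GrayLevelNonUniformity",
                           "GLRLM_RunLengthGLN", "FirstOrder_MAD",
                           "FirstOrder_RMS")

#' Texture feature table over images and regions
#'
#' Computes the five supported features (GLCM joint entropy, GLRLM gray
#' level and run-length non-uniformities, first-order MAD and RMS) on every
#' (image, region) crop.
#'
#' @param dataset a `phantom_dataset`, or an `n x H x W` image array.
#' @param boxes per-image boxes (defaults to the dataset's own boxes).
#' @param regions optional subset of region names.
#' @param n_gray gray levels for discretization.
#' @return long data.frame: `image_id`, `region`, `feature`, `value`.
#' @export
feature_table <- function(dataset, boxes = NULL, regions = NULL,
                          n_gray = 32L) {
  images <- as_image_array(dataset)
  boxes <- normalize_boxes(boxes %||% dataset$boxes, dim(images)[1])
  out <- vector("list", dim(images)[1])
  for (i in seq_len(dim(images)[1])) {
    bx <- boxes[[i]]
    if (!is.null(regions)) bx <- bx[bx$region %in% regions, , drop = FALSE]
    vals <- lapply(seq_len(nrow(bx)), function(r) {
      crop <- region_crop(images[i, , ],
                          c(bx$x0[r], bx$y0[r], bx$x1[r], bx$y1[r]),
                          n_gray = n_gray)
      nu <- glrlm_nonuniformities(crop)
      fo <- first_order(crop)
      data.frame(image_id = i, region = bx$region[r],
                 feature = radiomics_feature_ids,
                 value = c(glcm_joint_entropy(crop), nu["gln"], nu["rln"],
                           fo["mad"], fo["rms"]),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, vals)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlate a kernel's norms with a region texture feature
#'
#' Pearson (default) or Spearman correlation between the kernel's per-image
#' L1 norms and the feature values of one region across images, with the
#' fitted least-squares line. Either variable having zero variance makes
#' the correlation undefined; it is reported as NA.
#'
#' @param norms a `kernel_norm_table`.
#' @param features a [feature_table()] data.frame.
#' @param kernel kernel id or two-letter code.
#' @param region region name.
#' @param feature feature id (one of the table's `feature` values).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `n`, `slope`, `intercept`, plus identifiers.
#' @export
correlate_norms <- function(norms, features, kernel, region,
                            feature = "GLCM_JointEntropy",
                            method = c("pearson", "spearman")) {
  stopifnot(inherits(norms, "kernel_norm_table"))
  method <- match.arg(method)
  kcol <- if (is.character(kernel)) match(kernel, colnames(norms$norms))
          else as.integer(kernel)
  if (is.na(kcol) || kcol < 1 || kcol > ncol(norms$norms))
    stopf("unknown kernel: %s", as.character(kernel))
  f <- features[features$region == region & features$feature == feature, ]
  idx <- match(f$image_id, norms$image_ids)
  ok <- !is.na(idx)
  x <- norms$norms[idx[ok], kcol]
  y <- f$value[ok]
  if (length(x) < 3) stopf("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_; slope <- NA_real_; intercept <- NA_real_
  } else {
    r <- stats::cor(x, y, method = method)
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  list(kernel = colnames(norms$norms)[kcol], region = region,
       feature = feature, method = method, r = r, n = length(x),
       slope = slope, intercept = intercept)
}
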