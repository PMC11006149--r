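# Concept assignment: upsample kernel activation maps to image resolution,
# box the strongly activated pixels, score IOU hits against per-image
# region boxes and aggregate hit rates into kernel -> region assignments.

UNINTERPRETABLE <- "UNINTERPRETABLE"

#' Axis-aligned region box
#'
#' 0-based, half-open pixel bounds (`x0 <= x < x1`, `y0 <= y < y1`).
#'
#' @param x0,y0,x1,y1 bounds with `x0 < x1`, `y0 < y1`.
#' @param region optional region name.
#' @return named numeric vector of class `region_box`.
#' @export
region_box <- function(x0, y0, x1, y1, region = NA_character_) {
  if (x0 >= x1 || y0 >= y1) stopf("degenerate box: need x0 < x1 and y0 < y1")
  structure(c(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
            region = region, class = "region_box")
}

#' Intersection over union of two boxes
#'
#' Half-open semantics: a box's pixel area is `(x1 - x0) * (y1 - y0)`.
#' Symmetric, in \[0, 1\]; 1 iff the boxes are identical and 0 iff disjoint.
#'
#' @param a,b boxes as [region_box()] or numeric `c(x0, y0, x1, y1)`.
#' @return IOU fraction.
#' @export
iou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  ix <- min(a[3], b[3]) - max(a[1], b[1])
  iy <- min(a[4], b[4]) - max(a[2], b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# upsample a small activation map to image resolution
upsample_map <- function(map, image_size, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  EBImage::resize(map, w = image_size, h = image_size,
                  filter = if (interp == "bilinear") "bilinear" else "none")
}

#' Bounding box of a kernel's strongly activated pixels
#'
#' The activation map is upsampled to image resolution and thresholded at
#' the given percentile of its own values; the tight bounding box of the
#' positive pixels at or above the threshold is returned. An all-zero map
#' yields `NULL`: the kernel is silent for that image.
#'
#' @param map one kernel's activation matrix (rows = y).
#' @param image_size target (square) image side in pixels.
#' @param percentile percentile (0-100) defining "strongly activated".
#' @param interp upsampling interpolation, `"bilinear"` or `"nearest"`.
#' @return a [region_box()] in image coordinates, or `NULL`.
#' @export
activation_box <- function(map, image_size, percentile = 95,
                           interp = c("bilinear", "nearest")) {
  map <- as.matrix(map)
  if (anyNA(map) || any(!is.finite(map))) stopf("activation map is not finite")
  up <- upsample_map(map, image_size, match.arg(interp))
  thr <- stats::quantile(up, percentile / 100, names = FALSE)
  hot <- which(up >= thr & up > 0, arr.ind = TRUE)
  if (!nrow(hot)) return(NULL)
  region_box(x0 = min(hot[, 2]) - 1L, y0 = min(hot[, 1]) - 1L,
             x1 = max(hot[, 2]), y1 = max(hot[, 1]))
}

# normalize per-image boxes input: list of data.frames, a single shared
# data.frame, or a boxes CSV read by read_boxes()
normalize_boxes <- function(boxes, n_images) {
  if (is.data.frame(boxes)) boxes <- rep(list(boxes), n_images)
  if (length(boxes) < n_images) {
    missing <- setdiff(seq_len(n_images), seq_along(boxes))
    stopf("missing region boxes for image(s): %s",
          paste(utils::head(missing, 10), collapse = ", "))
  }
  boxes
}

#' Assign anatomical-region concepts to kernels via IOU hit rates
#'
#' For every image and kernel, the kernel's activation box is compared with
#' each region box; a hit is an IOU strictly above `iou_min`. Hit rates are
#' aggregated over all images of the split (images where the kernel is
#' silent count as misses). A kernel is assigned the region with the
#' highest hit rate provided that rate exceeds `hit_frac`; kernels with no
#' region above `hit_frac`, or with more than `max_regions` regions above
#' it, are `UNINTERPRETABLE`. Ties on the maximum rate break by region name
#' order; when two regions qualify, both are recorded and the maximum is
#' assigned.
#'
#' @param activations an `activation_set`.
#' @param boxes per-image region boxes: the `boxes` element of a
#'   `phantom_dataset`, a list of data.frames, or one shared data.frame.
#' @param iou_min IOU threshold for a per-image hit.
#' @param hit_frac dataset-wide hit-rate threshold for interpretability.
#' @param max_regions maximum number of highly-hit regions allowed.
#' @param percentile,interp passed to [activation_box()].
#' @param image_size image side in pixels; inferred from the boxes when
#'   omitted (maximum x1/y1 rounded up to the map grid).
#' @return object of class `concept_map`: data.frame `assignment` (kernel,
#'   code, region, hit_rate), matrix `hit_rates` (kernel x region), list
#'   `qualifying` and the thresholds used.
#' @export
assign_concepts <- function(activations, boxes, iou_min = 0.5,
                            hit_frac = 0.70, max_regions = 2,
                            percentile = 95,
                            interp = c("bilinear", "nearest"),
                            image_size = NULL) {
  stopifnot(inherits(activations, "activation_set"))
  interp <- match.arg(interp)
  acts <- activations$activations
  n <- dim(acts)[1]; K <- dim(acts)[2]
  boxes <- normalize_boxes(boxes, n)
  regions <- sort(unique(unlist(lapply(boxes[seq_len(n)],
                                       function(b) b$region))))
  if (is.null(image_size)) {
    mx <- max(vapply(boxes[seq_len(n)], function(b) max(b$x1, b$y1), 0))
    ms <- activations$map_size
    image_size <- as.integer(ceiling(mx / ms) * ms)
  }
  hits <- matrix(0, K, length(regions), dimnames = list(NULL, regions))
  for (i in seq_len(n)) {
    bx <- boxes[[i]]
    for (k in seq_len(K)) {
      ab <- activation_box(acts[i, k, , ], image_size,
                           percentile = percentile, interp = interp)
      if (is.null(ab)) next
      for (r in seq_len(nrow(bx))) {
        rb <- c(bx$x0[r], bx$y0[r], bx$x1[r], bx$y1[r])
        if (iou(ab, rb) > iou_min)
          hits[k, bx$region[r]] <- hits[k, bx$region[r]] + 1
      }
    }
  }
  rates <- hits / n
  codes <- kernel_codes(K)
  assigned <- character(K)
  qualifying <- vector("list", K)
  for (k in seq_len(K)) {
    qual <- colnames(rates)[rates[k, ] > hit_frac]
    qualifying[[k]] <- qual
    if (length(qual) < 1 || length(qual) > max_regions) {
      assigned[k] <- UNINTERPRETABLE
    } else {
      rq <- rates[k, qual]
      assigned[k] <- qual[order(-rq, qual)][1]
    }
  }
  best_rate <- apply(rates, 1, function(z) if (length(z)) max(z) else 0)
  structure(list(
    assignment = data.frame(kernel = seq_len(K), code = codes,
                            region = assigned, hit_rate = best_rate,
                            stringsAsFactors = FALSE),
    hit_rates = rates, qualifying = qualifying,
    params = list(iou_min = iou_min, hit_frac = hit_frac,
                  max_regions = max_regions, percentile = percentile,
                  interp = interp, image_size = image_size)
  ), class = "concept_map")
}

#' @export
print.concept_map <- function(x, ...) {
  interp <- x$assignment$region != UNINTERPRETABLE
  cat(sprintf("concept_map: %d/%d kernels interpretable (iou > %.2f, hit rate > %.2f)\n",
              sum(interp), nrow(x$assignment), x$params$iou_min,
              x$params$hit_frac))
  for (i in which(interp))
    cat(sprintf("  %s -> %s (hit rate %.2f)\n", x$assignment$code[i],
                x$assignment$region[i], x$assignment$hit_rate[i]))
  invisible(x)
}

#' Interpretable kernel ids of a concept map
#'
#' @param concepts a `concept_map`.
#' @return integer kernel ids with an assigned region.
#' @export
interpretable_kernels <- function(concepts) {
  stopifnot(inherits(concepts, "concept_map"))
  concepts$assignment$kernel[concepts$assignment$region != UNINTERPRETABLE]
}

#' Restrict a literal table to interpretable kernels
#'
#' Column subset in the original order; errors when no kernel is
#' interpretable, since rule induction would then have an empty vocabulary.
#'
#' @param literals a `literal_table`.
#' @param concepts a `concept_map` over the same kernels.
#' @return the filtered `literal_table`; kernel codes are preserved.
#' @export
filter_interpretable <- function(literals, concepts) {
  stopifnot(inherits(literals, "literal_table"))
  keep <- interpretable_kernels(concepts)
  if (ncol(literals$literals) != nrow(concepts$assignment))
    stopf("literal table and concept map kernel counts differ")
  if (!length(keep)) stopf("no interpretable kernels to keep")
  out <- literals
  out$literals <- literals$literals[, keep, drop = FALSE]
  if (!is.null(out$thresholds)) {
    th <- as.numeric(out$thresholds)[keep]
    out$thresholds <- structure(th,
                                provenance = attr(literals$thresholds,
                                                  "provenance"),
                                class = "threshold_vector")
  }
  out$kernel_ids <- keep
  out
}

#' Export a concept map to CSV
#'
#' One row per kernel: code, assigned region (or UNINTERPRETABLE) and the
#' per-region hit rates.
#'
#' @param concepts a `concept_map`.
#' @param path output CSV path.
#' @export
write_concepts_csv <- function(concepts, path) {
  stopifnot(inherits(concepts, "concept_map"))
  df <- cbind(concepts$assignment,
              as.data.frame(concepts$hit_rates, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
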