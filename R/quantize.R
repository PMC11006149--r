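# Quantization of kernel activations into logical literals:
# per-image L1 norms, per-kernel mean thresholds over the training split,
# and strict-threshold binarization to {-1, +1}.

#' Per-image, per-kernel L1 activation norms
#'
#' For every image i and kernel k, the kernel norm is the L1 norm (sum of
#' absolute values) of the activation map of kernel k on image i. No
#' normalization by map size is applied.
#'
#' @param activations an `activation_set` (or a plain `n x K` numeric
#'   matrix of precomputed norms, passed through).
#' @param labels optional 0/1 labels attached for plotting/analysis only.
#' @return object of class `kernel_norm_table`: list with `norms`
#'   (`n x K` matrix, columns named by [kernel_codes()]), `image_ids`,
#'   `labels`, `provenance`.
#' @export
kernel_norms <- function(activations, labels = NULL) {
  if (inherits(activations, "activation_set")) {
    a <- activations$activations
    if (anyNA(a) || any(!is.finite(a))) stopf("activations contain NaN/Inf")
    norms <- apply(abs(a), c(1, 2), sum)
    image_ids <- activations$image_ids
  } else {
    norms <- as.matrix(activations)
    if (anyNA(norms) || any(!is.finite(norms))) stopf("norms contain NaN/Inf")
    image_ids <- seq_len(nrow(norms))
  }
  colnames(norms) <- kernel_codes(ncol(norms))
  structure(list(norms = norms, image_ids = image_ids, labels = labels,
                 provenance = "L1 norm of activation maps"),
            class = "kernel_norm_table")
}

#' @export
print.kernel_norm_table <- function(x, ...) {
  cat(sprintf("kernel_norm_table: %d images x %d kernels\n",
              nrow(x$norms), ncol(x$norms)))
  invisible(x)
}

#' Per-kernel binarization thresholds
#'
#' The threshold of kernel k is the arithmetic mean of its norm over the
#' training set. Thresholds are computed once on the training split and
#' frozen; validation data is binarized with training thresholds.
#'
#' @param train_norms a `kernel_norm_table` computed on the training split.
#' @return object of class `threshold_vector`: named numeric vector with a
#'   `provenance` attribute.
#' @export
compute_thresholds <- function(train_norms) {
  stopifnot(inherits(train_norms, "kernel_norm_table"))
  if (nrow(train_norms$norms) < 1) stopf("empty norm table")
  theta <- colMeans(train_norms$norms)
  structure(theta, provenance = "mean over training set",
            class = "threshold_vector")
}

#' Binarize kernel norms into literals
#'
#' A kernel's literal for an image is +1 when its norm strictly exceeds the
#' kernel's threshold and -1 otherwise (ties at the threshold give -1).
#'
#' @param norms a `kernel_norm_table`.
#' @param thresholds a `threshold_vector` of matching length (computed on
#'   the training split).
#' @return object of class `literal_table`: list with `literals` (`n x K`
#'   matrix of -1/+1, columns named by kernel code), `thresholds`,
#'   `image_ids`, `labels`.
#' @export
binarize <- function(norms, thresholds) {
  stopifnot(inherits(norms, "kernel_norm_table"),
            inherits(thresholds, "threshold_vector"))
  if (ncol(norms$norms) != length(thresholds))
    stopf("norm table has %d kernels but threshold vector has %d",
          ncol(norms$norms), length(thresholds))
  b <- ifelse(sweep(norms$norms, 2, as.numeric(thresholds), `>`), 1, -1)
  colnames(b) <- colnames(norms$norms)
  structure(list(literals = b, thresholds = thresholds,
                 image_ids = norms$image_ids, labels = norms$labels),
            class = "literal_table")
}

#' @export
print.literal_table <- function(x, ...) {
  cat(sprintf("literal_table: %d images x %d kernels (+1: %.1f%%)\n",
              nrow(x$literals), ncol(x$literals),
              100 * mean(x$literals == 1)))
  invisible(x)
}

# construct a literal_table from a plain matrix (used by tests and when
# importing externally produced literals); values must be -1/+1
as_literal_table <- function(mat, labels = NULL) {
  mat <- as.matrix(mat)
  if (!all(mat %in% c(-1, 1))) stopf("literals must be -1/+1")
  if (is.null(colnames(mat))) colnames(mat) <- kernel_codes(ncol(mat))
  structure(list(literals = mat, thresholds = NULL,
                 image_ids = seq_len(nrow(mat)), labels = labels),
            class = "literal_table")
}

#' Export norm or literal tables to CSV
#'
#' Rows are images, columns kernels (by code), plus an optional `label`
#' column; this is the data behind kernel norm plots.
#'
#' @param x a `kernel_norm_table` or `literal_table`.
#' @param path output CSV path.
#' @export
write_table_csv <- function(x, path) {
  mat <- if (inherits(x, "kernel_norm_table")) x$norms
         else if (inherits(x, "literal_table")) x$literals
         else stopf("unsupported table type")
  df <- data.frame(image_id = x$image_ids, mat, check.names = FALSE)
  if (!is.null(x$labels)) df$label <- x$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
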