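# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Stable two-letter display codes for kernels
#'
#' Kernels are referred to in rules by short two-letter codes (AA, AB, ...),
#' assigned by kernel index. The codes carry no meaning beyond readability.
#'
#' @param k number of kernels.
#' @return character vector of length `k`.
#' @export
kernel_codes <- function(k) {
  stopifnot(k >= 1, k <= 26 * 26)
  i <- seq_len(k) - 1L
  paste0(LETTERS[i %/% 26L + 1L], LETTERS[i %% 26L + 1L])
}

# validate a binary 0/1 vector
check_binary <- function(x, what = "targets") {
  if (!all(x %in% c(0L, 1L))) stopf("%s must be binary 0/1", what)
  as.integer(x)
}
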