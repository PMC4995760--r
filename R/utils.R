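#' Raw median absolute deviation
#'
#' Median of absolute deviations from the median, without the 1.4826
#' normal-consistency factor. Used by the cell QC rule and the Fano-factor
#' filter, both of which are stated in plain MAD units.
#'
#' @param x numeric vector.
#' @return a single non-negative number.
#' @export
mad_raw <- function(x) {
  stats::median(abs(x - stats::median(x)))
}

#' Derive a per-task seed from a master seed and a string key
#'
#' Deterministic 32-bit hash so that each projection configuration (or other
#' named sub-task) gets its own reproducible RNG stream regardless of
#' execution order.
#'
#' @param master_seed integer master seed.
#' @param key character key naming the sub-task.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, key) {
  m <- 2147483629
  h <- as.numeric(master_seed) %% m
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% m
  as.integer(h + 1)
}

# internal: stop unless x is a numeric matrix with unique dimnames
check_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must have gene rownames and cell colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate cell ids", call. = FALSE)
  if (any(!is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  if (any(x < 0)) stop(what, " contains negative values", call. = FALSE)
  invisible(x)
}
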