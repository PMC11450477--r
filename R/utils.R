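#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (the convention of
#' the printed survey tables, e.g. 277/665 -> 41.65), rather than base
#' R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' roundHalfUp(100 * 277 / 665, 2)  # 41.65
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# upper-triangle index pairs of a p x p matrix, as a 2-column matrix
.pairIndices <- function(p) {
  if (p < 2L) return(matrix(integer(), 0L, 2L))
  ij <- which(upper.tri(diag(p)), arr.ind = TRUE)
  ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

# deterministic derived seeds that stay within 32-bit integer range
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12347) %% 2147483647)
}
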