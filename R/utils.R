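#' Round a value half-up at a number of significant digits
#'
#' Base `signif()` rounds half-to-even; published tables are normally
#' formatted with half-up rounding of the significand, so reconstruction of
#' printed statistics needs the half-up convention.
#'
#' @param x numeric vector.
#' @param digits number of significant digits (>= 1).
#' @return `x` rounded half-up on the significand.
#' @export
#' @examples
#' signif_half_up(0.0835, 2) # 0.084
signif_half_up <- function(x, digits) {
  stopifnot(digits >= 1)
  out <- x
  nz <- !is.na(x) & is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz])))
  f <- 10^(e - digits + 1)
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) / f + 0.5) * f
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L))) {
    stop("expected a 2x2 table", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("table cells must be non-negative integers", call. = FALSE)
  }
  invisible(table)
}
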