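#' Round half away from zero at a fixed number of decimals
#'
#' Display rounding used for all reported percentages and counts: exact halves
#' round up (9.85 -> 9.9), unlike [base::round()]'s round-half-even. Internal
#' arithmetic is never rounded; this is applied only at the reporting surface.
#'
#' @param x numeric vector.
#' @param digits decimals to keep (0 for integers).
#' @return `x` rounded half-up.
#' @export
#' @examples
#' round_half_up(c(12.65, 12.749, 0.5), 1)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by an ulp-scale epsilon so values that are exact halves in decimal
  # but stored just below in binary (e.g. 23.485 * 10) still round up
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bct <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) if (!isTRUE(cond)) stop_bct(...)

#' @noRd
logistic <- function(x) plogis(x)
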