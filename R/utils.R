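# Small shared numerics. All internal.

#' Cumulative trapezoid integral of y over x, anchored at 0.
#' @noRd
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(0)
  c(0, cumsum(diff(x) * (y[-n] + y[-1]) / 2))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sentinel for "threshold never reached" results.
#' @noRd
no_cure <- function() Inf

#' @noRd
is_no_cure <- function(x) !is.finite(x)

#' Stable positive root of a*x^2 + b*x - c = 0 (a, c >= 0, b >= 0).
#' @noRd
quad_pos_root <- function(a, b, c) {
  # x = 2c / (b + sqrt(b^2 + 4ac)): no cancellation for b^2 >> 4ac
  ifelse(c <= 0, 0, 2 * c / (b + sqrt(b * b + 4 * a * c)))
}

#' expm1-safe (1 - exp(-x))/x with the x -> 0 limit.
#' @noRd
rexpm1 <- function(x) ifelse(abs(x) < 1e-12, 1 - x / 2, -expm1(-x) / x)

#' Round for text output at fixed significant digits (CSV contract).
#' @noRd
sig12 <- function(x) signif(x, 12)
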