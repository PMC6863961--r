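# Gel/viscosity effect: as conversion raises viscosity, free volume drops
# and both propagation (kp) and termination (kT) slow. The empirical (Wu)
# forms below are in CGS-style units (cm3/mM/s); the numeric tiers apply
# them as ratios to the preset constants, and the analytic layer uses the
# separate m-corrected effective K (never both at once).

#' Conversion-dependent propagation and termination constants
#'
#' `E' = exp(v C_EFF)`; `kp = 1865 / (1 + 2e-9 E')`;
#' `kT = 1e7 / (2.3 + E') + kp (1 - C_EFF)`.
#'
#' @param C_EFF conversion efficacy in `[0, 1)` (vectorized).
#' @param v viscosity strength exponent (typical 25-40).
#' @return list with vectors `kp` and `kT`.
#' @export
#' @examples
#' rates_vs_conversion(0, 28)$kp  # 1865 to 6 significant figures
rates_vs_conversion <- function(C_EFF, v) {
  if (any(C_EFF < 0 | C_EFF >= 1)) stop("C_EFF must be in [0, 1)")
  if (any(v < 0)) stop("v must be non-negative")
  Ep <- exp(v * C_EFF)
  kp <- 1865 / (1 + 2e-9 * Ep)
  kT <- 1e7 / (2.3 + Ep) + kp * (1 - C_EFF)
  list(kp = kp, kT = kT)
}

#' Viscosity attenuation ratios relative to zero conversion
#'
#' Used by the numeric tiers to rescale whatever preset (kp, kT) are in
#' force; only the shape of the slowdown, not the absolute Wu magnitudes,
#' carries over.
#'
#' @param C_EFF conversion efficacy in `[0, 1)`.
#' @param v viscosity strength exponent.
#' @return list with vectors `kp` and `kT` of attenuation factors (= 1 at
#'   `C_EFF = 0`).
#' @export
viscosity_scale <- function(C_EFF, v) {
  r0 <- rates_vs_conversion(0, v)
  r <- rates_vs_conversion(C_EFF, v)
  list(kp = r$kp / r0$kp, kT = r$kT / r0$kT)
}

#' m-corrected effective rate constant multiplier
#'
#' The analytic layer's viscosity correction: K is shrunk by
#' `1 - m (1 - exp(-S))`, with `S` the first-order (uncorrected) exponent,
#' saturating at `1 - m` for full conversion.
#'
#' @param S_first_order the uncorrected S value(s), >= 0.
#' @param m correction amplitude in `[0, 1)` (fit parameter, typical
#'   0.1-0.3).
#' @return Multiplier(s) in `(1 - m, 1]`.
#' @export
effective_K_correction <- function(S_first_order, m) {
  if (any(S_first_order < 0)) stop("S must be non-negative")
  if (m < 0 || m >= 1) stop("m must be in [0, 1)")
  1 - m * (1 - exp(-S_first_order))
}
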