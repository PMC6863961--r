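# Analytic (closed-form) layer: conversion efficacy 1 - exp(-S), the
# accumulated exponent S, closed-form oxygen decays, the induction time,
# and scaling-law diagnostics. Under bimolecular termination the radical
# scales as sqrt of the initiation rate, which is what produces the
# characteristic (C0 I0)^0.5 t transient and (C0/I0)^0.5 steady-state
# scaling (and the failure of dose reciprocity).

#' Conversion efficacy from the accumulated exponent
#'
#' `C_EFF = 1 - [A]/[A]0 = 1 - exp(-S)`.
#'
#' @param S accumulated exponent(s), >= 0.
#' @return Efficacy in `[0, 1)`.
#' @export
#' @examples
#' efficacy_from_S(2)      # 0.8647, the S_T = 2 curing threshold
#' efficacy_from_S(log(5)) # 0.8, the numeric-layer threshold
efficacy_from_S <- function(S) {
  if (any(S < 0)) stop("S must be non-negative")
  -expm1(-S)
}

#' Oxygen induction time (linear-depletion closed form)
#'
#' `T_ID = pi k Y0 / (4 kp B)`: the zero crossing of the linear oxygen
#' decay [oxygen_linear()]. `k_ratio` is the dimensionless carrier constant
#' of the depletion law (default 1).
#'
#' @param Y0 initial oxygen, mM.
#' @param B radical drive `b_exc I C`, mM/s.
#' @param kp propagation constant.
#' @param k_ratio carrier constant k.
#' @return T_ID in s; 0 when `Y0 = 0`; `Inf` (no-cure sentinel) when the
#'   drive vanishes.
#' @export
induction_time <- function(Y0, B, kp, k_ratio = 1) {
  if (any(Y0 < 0)) stop("Y0 must be >= 0")
  out <- pi * k_ratio * Y0 / (4 * kp * B)   # recycles over its arguments
  out[out == Inf | is.nan(out)] <- no_cure()
  out[Y0 == 0] <- 0
  out
}

#' Linear pre-induction oxygen decay
#'
#' `[O2](t) = max(0, Y0 - 4 kp B t / (pi k))`; reaches zero exactly at
#' [induction_time()].
#'
#' @param t time(s), s.
#' @param Y0 initial oxygen, mM.
#' @param kp propagation constant.
#' @param B radical drive, mM/s.
#' @param k_ratio carrier constant k.
#' @return Oxygen concentration(s), mM.
#' @export
oxygen_linear <- function(t, Y0, kp, B, k_ratio = 1) {
  if (any(t < 0)) stop("t must be >= 0")
  pmax(0, Y0 - 4 * kp * B * t / (pi * k_ratio))
}

#' Exponential oxygen decay from an accumulated exponent
#'
#' `[O2](t) = Y0 exp(-S'(t))` with `S'` the accumulated scavenging exponent
#' (the integral of the inhibition rate over the radical history).
#'
#' @param t times, s.
#' @param Y0 initial oxygen, mM.
#' @param S_prime either a non-decreasing numeric vector matching `t`, or a
#'   function of t.
#' @return Oxygen concentration(s), mM.
#' @export
oxygen_exponential <- function(t, Y0, S_prime) {
  s <- if (is.function(S_prime)) vapply(t, S_prime, 0) else S_prime
  if (length(s) != length(t)) stop("S_prime must match t")
  if (any(s < 0)) stop("S' must be non-negative")
  if (any(diff(s) < -1e-12)) stop("S' must be non-decreasing")
  Y0 * exp(-s)
}

# ---- the S-function --------------------------------------------------------

#' @noRd
analytic_coefs <- function(params, z,
                           A1_variant = c("none", "as_printed",
                                          "consistent")) {
  A1_variant <- match.arg(A1_variant)
  o <- params$optics; I0 <- params$irr$I0; C0 <- params$init$C0
  a1_coef <- 2.3 * (o$a_ps - o$b_prod) * C0 * I0 * o$b_exc
  list(
    K = params$derived$K,
    b = o$b_exc, I0 = I0, C0 = C0,
    A2 = params$derived$A2, A_avg = params$derived$A_avg,
    X = exp(-params$derived$A2 * z),
    Xq = exp(-params$derived$A_avg * z),
    Bp = o$b_exc * I0 * exp(-params$derived$A_avg * z),
    A1 = switch(A1_variant, none = 0 * z, as_printed = a1_coef * z,
                consistent = a1_coef + 0 * z)
  )
}

#' Accumulated exponent S(z, t) of the conversion efficacy
#'
#' Closed form (per depth z, exposure time t):
#' `S = K sqrt(0.5 b I0 C0 X) [1 - exp(-B'' t'')] / B''` with
#' `X = exp(-A2 z)`, `B'' = 0.5 (B' - 0.5 A1 t)`,
#' `B' = b I0 exp(-A'' z)`, and `t'' = max(0, t - t_ind)`. The quadrature
#' variant evaluates `S = kp int_0^t (sqrt(0.5 B/kT) - K12 [O2]) dt'` with
#' `B = b I(z,t') C(z,t')` from the analytic light/PS fields; the oxygen
#' correction `K12 [O2]` (with `K12 = ki (1 - B')/(4 kT)` and the linear
#' pre-induction oxygen decay) is off by default, mirroring the
#' type-I-dominant closed form. When `B'' <= 0` (dynamic-absorption
#' overshoot) the `B'' -> 0` limit `S ~ t''` is used.
#'
#' The bundle's viscosity `m`-correction, if enabled, shrinks K by
#' [effective_K_correction()] evaluated at the first-order (uncorrected) S.
#'
#' @param params a `pp_params` bundle.
#' @param z depth(s), cm.
#' @param t time(s), s.
#' @param variant `"closed_form"` or `"quadrature"`.
#' @param A1_variant dynamic-absorption term: `"none"` (default, A1 = 0),
#'   `"as_printed"` (keeps the printed extra z factor), `"consistent"`.
#' @param t_ind induction time offset T_ID, s.
#' @param include_oxygen logical: subtract the `K12 [O2]` term (quadrature
#'   variant only).
#' @param k_ratio carrier constant of the linear oxygen decay.
#' @return Matrix `length(z) x length(t)` (dropped to a vector when either
#'   argument is scalar).
#' @export
s_function <- function(params, z, t, variant = c("closed_form", "quadrature"),
                       A1_variant = c("none", "as_printed", "consistent"),
                       t_ind = 0, include_oxygen = FALSE, k_ratio = 1) {
  variant <- match.arg(variant)
  A1_variant <- match.arg(A1_variant)
  stopifnot(inherits(params, "pp_params"))
  if (any(t < 0)) stop("t must be >= 0")
  cf <- analytic_coefs(params, z, A1_variant)
  m <- if (params$vis$enabled) params$vis$m else 0
  S <- if (variant == "closed_form") {
    s_closed(cf, z, t, t_ind, m)
  } else {
    s_quadrature(params, cf, z, t, t_ind, include_oxygen, k_ratio, m)
  }
  drop(S)
}

#' @noRd
s_closed <- function(cf, z, t, t_ind, m = 0) {
  nz <- length(z); nt <- length(t)
  pref <- cf$K * sqrt(0.5 * cf$b * cf$I0 * cf$C0 * cf$X)   # per z
  tpp <- pmax(0, t - t_ind)                                # per t
  A1t <- outer(cf$A1, t)
  Bpp <- 0.5 * (matrix(cf$Bp, nz, nt) - 0.5 * A1t)
  Tpp <- matrix(tpp, nz, nt, byrow = TRUE)
  # G = (1 - exp(-B'' t''))/B'', with the B'' -> 0 (and B'' < 0 overshoot)
  # limit G = t''
  G <- Tpp * rexpm1(pmax(Bpp, 0) * Tpp)
  S0 <- matrix(pref, nz, nt) * G
  if (m > 0) S0 <- S0 * effective_K_correction(S0, m)
  S0
}

#' @noRd
s_quadrature <- function(params, cf, z, t, t_ind, include_oxygen, k_ratio,
                         m = 0) {
  r <- params$rates
  Y0 <- params$init$Y0
  floor_A <- params$derived$A_floor
  nz <- length(z); nt <- length(t)
  S <- matrix(0, nz, nt)
  for (i in seq_len(nz)) {
    zi <- z[i]
    a1 <- cf$A1[i]
    bp <- cf$Bp[i]
    integrand <- function(tp) {
      Ap <- pmax(cf$A2 - a1 * tp, floor_A)
      I <- cf$I0 * exp(-Ap * zi)
      C <- cf$C0 * exp(-bp * tp)
      B <- cf$b * I * C
      val <- r$kp * sqrt(0.5 * B / r$kT)
      if (include_oxygen) {
        O2 <- oxygen_linear(tp, Y0, r$kp, cf$b * cf$I0 * cf$C0 * cf$X[i],
                            k_ratio)
        Bpr <- ifelse(B > 0, 0.5 * r$ki * O2 / sqrt(8 * B * r$kT), 0)
        K12 <- r$ki * (1 - pmin(Bpr, 1)) / (4 * r$kT)
        val <- val - r$kp * K12 * O2
      }
      pmax(val, 0)
    }
    for (j in seq_len(nt)) {
      upper <- max(0, t[j] - t_ind)
      if (upper == 0) { S[i, j] <- 0; next }
      S[i, j] <- integrate(integrand, 0, upper, rel.tol = 1e-10,
                           abs.tol = 1e-14, subdivisions = 500L)$value
    }
  }
  if (m > 0) S <- S * effective_K_correction(S, m)
  S
}

#' Fit a power-law scaling exponent in log-log space
#'
#' Least-squares slope of `log(quantity)` against `log(driver)`; the
#' diagnostic used for the `(C0 I0 t^2)^0.5` transient and `(C0/I0)^0.5`
#' steady-state scaling laws.
#'
#' @param quantity positive response samples.
#' @param driver positive driver samples (same length, >= 4 values spanning
#'   at least one decade recommended).
#' @return The fitted exponent (slope).
#' @export
fit_scaling_exponent <- function(quantity, driver) {
  if (length(quantity) != length(driver)) stop("length mismatch")
  if (length(quantity) < 2) stop("need at least two samples")
  if (any(quantity <= 0) || any(driver <= 0)) {
    stop("samples must be positive for log-log fitting")
  }
  unname(coef(lm(log(quantity) ~ log(driver)))[2])
}
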