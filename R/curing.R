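# Curing depth and inhibition zone. A point is "cured" once its efficacy
# exceeds the threshold C_T, i.e. S > S_T = ln[1/(1 - C_T)]. The curing
# time T_C(z) inverts the monotone S(z, .); the curing depth Z_C(t) inverts
# it in z; the inhibition zone is the uncured remainder H - Z_C.

#' Threshold exponent from threshold efficacy
#' @param C_T threshold efficacy in `[0, 1)`.
#' @return `S_T = ln[1/(1 - C_T)]`.
#' @export
threshold_exponent <- function(C_T) {
  if (any(C_T < 0 | C_T >= 1)) stop("C_T must be in [0, 1)")
  -log1p(-C_T)
}

#' Curing time at a given depth
#'
#' Smallest exposure time with `S(z, t) >= S_T`. Method `"root"` (the
#' authoritative definition) brackets and bisects the monotone closed-form
#' S; `"closed_form"` inverts it analytically,
#' `T_C = t_ind + (1/B'') ln[1 / (1 - S_T B'' / (K sqrt(0.5 b X I0 C0)))]`,
#' polishing by fixed point when the dynamic-absorption or m-correction
#' terms make the coefficients time dependent. Both return the no-cure
#' sentinel `Inf` when the steady-state exponent stays below `S_T`.
#'
#' @param z depth, cm (scalar).
#' @param params a `pp_params` bundle.
#' @param method `"root"` or `"closed_form"`.
#' @param S_T threshold exponent (default 2, i.e. C_T = 0.86).
#' @param A1_variant,t_ind passed to [s_function()].
#' @param t_max bracket cap for the root search, s.
#' @return T_C in s (Inf = no cure).
#' @export
curing_time <- function(z, params, method = c("root", "closed_form"),
                        S_T = 2, A1_variant = "none", t_ind = 0,
                        t_max = 1e7) {
  method <- match.arg(method)
  stopifnot(inherits(params, "pp_params"))
  if (z < 0 || z > params$init$H + 1e-12) stop("z outside [0, H]")
  cf <- analytic_coefs(params, z, A1_variant)
  m <- if (params$vis$enabled) params$vis$m else 0
  pref <- cf$K * sqrt(0.5 * cf$b * cf$I0 * cf$C0 * cf$X)
  if (pref <= 0) return(no_cure())
  sfun <- function(t) s_function(params, z, t, variant = "closed_form",
                                 A1_variant = A1_variant, t_ind = t_ind)
  if (A1_variant == "none") {
    Bpp <- 0.5 * cf$Bp
    K_sat <- if (m > 0) 1 - m else 1  # most conservative K shrinkage
    S_inf <- K_sat * pref / Bpp
    if (Bpp > 0 && S_inf < S_T) {
      # the saturated exponent cannot reach the threshold
      S_inf_true <- sfun(t_max)
      if (S_inf_true < S_T) return(no_cure())
    }
  }
  if (method == "closed_form") {
    tc <- closed_form_tc(pref, cf, z, t_ind, S_T, m)
    if (is_no_cure(tc)) return(no_cure())
    # the inversion must satisfy S(T_C) = S_T; polish when A1/m active
    if (m > 0 || A1_variant != "none") {
      for (k in 1:60) {
        res <- sfun(tc) - S_T
        if (abs(res) < 1e-10 * S_T) break
        # secant-style polish on the monotone S
        dt <- max(1e-6, 1e-6 * tc)
        slope <- (sfun(tc + dt) - sfun(tc)) / dt
        if (slope <= 0) break
        tc <- max(t_ind, tc - res / slope)
      }
    }
    return(tc)
  }
  # root method: expand the bracket, then uniroot on the monotone S
  if (sfun(t_max) < S_T) return(no_cure())
  hi <- max(1, 2 * t_ind)
  while (sfun(hi) < S_T && hi < t_max) hi <- hi * 2
  hi <- min(hi, t_max)
  uniroot(function(t) sfun(t) - S_T, lower = t_ind, upper = hi,
          tol = 1e-12 * max(hi, 1))$root
}

#' @noRd
closed_form_tc <- function(pref, cf, z, t_ind, S_T, m) {
  Bpp <- 0.5 * cf$Bp
  K_eff <- if (m > 0) effective_K_correction(S_T, m) else 1
  arg <- S_T * Bpp / (K_eff * pref)
  if (Bpp <= 0) return(t_ind + S_T / (K_eff * pref))
  if (arg >= 1) return(no_cure())
  t_ind - log1p(-arg) / Bpp
}

#' Curing depth at a given exposure time
#'
#' Largest depth whose exponent has reached the threshold,
#' `Z_C(t) = max{ z : S(z, t) >= S_T }`; 0 when even the surface is uncured
#' and `H` when the whole film has cured. Located by a depth scan plus
#' bisection refinement (robust also when S is not strictly monotone in z).
#'
#' @param t exposure time, s (scalar or vector).
#' @param params a `pp_params` bundle.
#' @param S_T threshold exponent (default 2).
#' @param A1_variant,t_ind passed to [s_function()].
#' @param n_scan scan resolution in depth.
#' @return Z_C in cm (same length as `t`).
#' @export
curing_depth <- function(t, params, S_T = 2, A1_variant = "none",
                         t_ind = 0, n_scan = 257L) {
  stopifnot(inherits(params, "pp_params"))
  H <- params$init$H
  zs <- seq(0, H, length.out = n_scan)
  vapply(t, function(ti) {
    if (ti <= t_ind) return(0)
    Sv <- s_function(params, zs, ti, variant = "closed_form",
                     A1_variant = A1_variant, t_ind = t_ind)
    above <- Sv >= S_T
    if (!above[1]) return(0)
    if (all(above)) return(H)
    i <- max(which(above))           # last cured scan node
    if (i == n_scan) return(H)
    root <- uniroot(function(z) {
      s_function(params, z, ti, variant = "closed_form",
                 A1_variant = A1_variant, t_ind = t_ind) - S_T
    }, lower = zs[i], upper = zs[i + 1], tol = 1e-6 * H)$root
    root
  }, 0)
}

#' Steady-state curing time
#'
#' First exposure time at which the curing depth reaches `fraction * H`
#' (default 0.9, the convention used to compare with measured pillar
#' growth). Equal to the curing time at that depth for the monotone
#' closed-form S.
#'
#' @param params a `pp_params` bundle.
#' @param fraction depth fraction in `(0, 1]`.
#' @param ... passed to [curing_time()].
#' @return T_S in s (Inf = never reached).
#' @export
steady_state_time <- function(params, fraction = 0.9, ...) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  curing_time(fraction * params$init$H, params, method = "root", ...)
}

#' Inhibition zone (uncured remainder of the film)
#' @param Z_C curing depth, cm.
#' @param H film thickness, cm.
#' @return `Z_N = H - Z_C` in cm.
#' @export
inhibition_zone <- function(Z_C, H) {
  if (any(Z_C < 0)) stop("Z_C must be >= 0")
  if (any(Z_C > H + 1e-12)) stop("Z_C exceeds the film thickness H")
  pmax(H - Z_C, 0)
}

#' Curing depth from a simulated trajectory
#'
#' Per stored time, the largest depth whose (linearly interpolated)
#' efficacy exceeds the numeric threshold `C_T` (default 0.8).
#'
#' @param traj a `pp_trajectory` from any model tier.
#' @param C_T threshold efficacy.
#' @return Numeric vector `Z_C(t)` over the stored time grid, cm.
#' @export
curing_depth_numeric <- function(traj, C_T = 0.8) {
  stopifnot(inherits(traj, "pp_trajectory"))
  if (C_T < 0 || C_T >= 1) stop("C_T must be in [0, 1)")
  z <- traj$z
  apply(traj$efficacy, 2, function(eff) {
    above <- eff >= C_T
    if (!above[1]) return(0)
    if (all(above)) return(z[length(z)])
    i <- max(which(above))
    if (i == length(z)) return(z[length(z)])
    # linear interpolation of the crossing between nodes i and i+1
    e0 <- eff[i]; e1 <- eff[i + 1]
    if (e0 == e1) return(z[i])
    z[i] + (e0 - C_T) / (e0 - e1) * (z[i + 1] - z[i])
  })
}
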