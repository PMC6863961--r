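# Parameter containers and validation. Unit convention (fixed): mM, s, cm,
# mW/cm2. b_exc is in 1/(s mW/cm2), so b_exc * I is the first-order PS
# excitation rate; extinction coefficients in 1/(mM cm); background (monomer)
# absorption Q in 1/cm.

#' Optical parameters of the photosensitizer system
#'
#' @param a_ps molar extinction coefficient of the ground-state
#'   photosensitizer, 1/(mM cm).
#' @param b_prod molar extinction coefficient of the photolysis product,
#'   1/(mM cm).
#' @param Q background (monomer) absorption coefficient, 1/cm.
#' @param b_exc excitation rate coefficient per unit intensity,
#'   1/(s mW/cm2). If `NULL` it is derived as `derive_b_exc(a_ps, q, w)`;
#'   a directly supplied value wins over the derived one (a notice is given
#'   if both are available and differ).
#' @param q triplet-state quantum yield (dimensionless), optional.
#' @param w wavelength in cm, optional.
#' @return An object of class `pp_optics`.
#' @export
#' @examples
#' optical_params(a_ps = 458, b_exc = 0.02)
optical_params <- function(a_ps = 458, b_prod = 0, Q = 0, b_exc = NULL,
                           q = NULL, w = NULL) {
  chk_nonneg(c(a_ps = a_ps, b_prod = b_prod, Q = Q))
  derived <- if (!is.null(q) && !is.null(w)) derive_b_exc(a_ps, q, w) else NULL
  if (is.null(b_exc)) {
    if (is.null(derived)) {
      stop("supply b_exc directly or both q and w to derive it")
    }
    b_exc <- derived
  } else if (!is.null(derived) &&
             abs(b_exc - derived) > 1e-12 * max(abs(derived), 1)) {
    message("b_exc supplied directly (", b_exc, ") overrides derived value (",
            signif(derived, 6), ")")
  }
  chk_nonneg(c(b_exc = b_exc))
  structure(list(a_ps = a_ps, b_prod = b_prod, Q = Q, b_exc = b_exc,
                 q = q, w = w),
            class = "pp_optics")
}

#' Excitation coefficient from extinction, quantum yield and wavelength
#'
#' `b_exc = 83.6 * a_ps * q * w`, with the wavelength `w` in cm.
#'
#' @param a_ps ground-state extinction coefficient, 1/(mM cm).
#' @param q triplet quantum yield.
#' @param w wavelength, cm.
#' @return b_exc in 1/(s mW/cm2).
#' @export
derive_b_exc <- function(a_ps, q, w) {
  chk_nonneg(c(a_ps = a_ps, q = q, w = w))
  83.6 * a_ps * q * w
}

#' Reaction rate constants
#'
#' Bimolecular constants are in 1/(mM s); unimolecular relaxations (`k5`,
#' `k6`) in 1/s. The lumped effective constant `K = kp / sqrt(kT)` is stored
#' read-only and recomputed whenever constants change (see [modify_rates()]).
#'
#' @param kp radical-monomer propagation constant (the paper-level k').
#' @param kT bimolecular radical termination constant.
#' @param ki radical-oxygen inhibition (scavenging) constant (k'').
#' @param k12 cross-termination of the two radicals.
#' @param k3 triplet-oxygen quenching (singlet-oxygen production).
#' @param k5 triplet relaxation rate, 1/s.
#' @param k6 singlet-oxygen relaxation rate, 1/s.
#' @param k11 singlet-oxygen quenching by the ground-state PS.
#' @param k_tm triplet-monomer coupling (radical generation).
#' @param k_xm singlet-oxygen-monomer cross-linking.
#' @return An object of class `pp_rates` with derived field `K`.
#' @export
rate_constants <- function(kp = 1865, kT = 1e7 / 3.3 + 1865, ki = 2e5,
                           k12 = 1e3, k3 = 1e6, k5 = 1e4, k6 = 2.5e5,
                           k11 = 1e5, k_tm = 5e6, k_xm = 5e6) {
  vals <- c(kp = kp, kT = kT, ki = ki, k12 = k12, k3 = k3, k5 = k5,
            k6 = k6, k11 = k11, k_tm = k_tm, k_xm = k_xm)
  chk_nonneg(vals)
  r <- as.list(vals)
  r$K <- if (kT > 0) kp / sqrt(kT) else NA_real_
  structure(r, class = "pp_rates")
}

#' Modify rate constants, recomputing the effective constant K
#'
#' @param rates a `pp_rates` object.
#' @param ... named replacements, e.g. `kp = 900`.
#' @return The updated `pp_rates` with `K = kp / sqrt(kT)` recomputed.
#' @export
modify_rates <- function(rates, ...) {
  stopifnot(inherits(rates, "pp_rates"))
  upd <- list(...)
  bad <- setdiff(names(upd), setdiff(names(rates), "K"))
  if (length(bad)) stop("unknown rate constant(s): ", paste(bad, collapse = ", "))
  r <- modifyList(rates[setdiff(names(rates), "K")], upd)
  do.call(rate_constants, r)
}

#' Initial concentrations and film geometry
#'
#' @param C0 initial photosensitizer concentration, mM.
#' @param Y0 initial dissolved oxygen, mM.
#' @param A0 initial monomer concentration, mM (must be > 0).
#' @param H film thickness, cm.
#' @param P_max maximum oxygen replenishment rate P', mM/s (the source term
#'   is `P = (1 - O2/Y0) * P_max`).
#' @return An object of class `pp_init`.
#' @export
state_init <- function(C0, Y0 = 0.001, A0 = 0.02, H = 0.03, P_max = 0) {
  chk_nonneg(c(C0 = C0, Y0 = Y0, A0 = A0, H = H, P_max = P_max))
  if (A0 <= 0) stop("A0 must be positive")
  if (P_max > 0 && Y0 <= 0) {
    stop("P_max > 0 requires Y0 > 0 (the source term saturates at Y0)")
  }
  structure(list(C0 = C0, Y0 = Y0, A0 = A0, H = H, P_max = P_max),
            class = "pp_init")
}

#' Irradiation protocol and computational grids
#'
#' @param I0 surface intensity, mW/cm2.
#' @param t_end exposure duration, s.
#' @param z_grid strictly increasing depths starting at 0, cm. Default:
#'   `nz` uniform nodes over `[0, H]` (H supplied at bundle validation).
#' @param t_grid strictly increasing times starting at 0, s; default `nt`
#'   uniform points over `[0, t_end]`.
#' @param nz,nt grid sizes used when explicit grids are absent.
#' @return An object of class `pp_irr`.
#' @export
irradiation <- function(I0, t_end, z_grid = NULL, t_grid = NULL,
                        nz = 61L, nt = 101L) {
  chk_nonneg(c(I0 = I0, t_end = t_end))
  if (!is.null(z_grid)) chk_grid(z_grid, "z_grid", from_zero = TRUE)
  if (!is.null(t_grid)) chk_grid(t_grid, "t_grid", from_zero = TRUE)
  structure(list(I0 = I0, t_end = t_end, z_grid = z_grid, t_grid = t_grid,
                 nz = as.integer(nz), nt = as.integer(nt)),
            class = "pp_irr")
}

#' Viscosity (gel-effect) parameters
#'
#' @param v viscosity strength exponent in `E' = exp(v * C_EFF)`
#'   (dimensionless, typical 25-40; 0 disables the effect).
#' @param m effective-K correction amplitude for the analytic layer,
#'   in `[0, 1)`.
#' @param enabled logical; defaults to `v > 0 || m > 0`.
#' @return An object of class `pp_vis`.
#' @export
viscosity_params <- function(v = 0, m = 0, enabled = NULL) {
  chk_nonneg(c(v = v, m = m))
  if (m >= 1) stop("m must be in [0, 1)")
  structure(list(v = v, m = m, enabled = enabled %||% (v > 0 || m > 0)),
            class = "pp_vis")
}

#' Validate and assemble a parameter bundle
#'
#' Checks every invariant (non-negativity, grid monotonicity, division
#' guards), fills default grids, and attaches derived constants: the
#' effective rate constant `K = kp/sqrt(kT)`, the initial absorption
#' `A2 = 2.3 (a_ps C0 + Q)` and the averaged absorption
#' `A'' = 1.15 (a_ps + b_prod) C0 + 2.3 Q`.
#'
#' @param optics a `pp_optics`.
#' @param rates a `pp_rates`.
#' @param init a `pp_init`.
#' @param irr a `pp_irr`.
#' @param vis a `pp_vis` (optional; defaults to disabled).
#' @return A validated bundle of class `pp_params`.
#' @export
#' @examples
#' p <- validate_params(optical_params(b_exc = 0.02),
#'                      rate_constants(),
#'                      state_init(C0 = 0.01),
#'                      irradiation(I0 = 5, t_end = 100))
#' p$derived$K
validate_params <- function(optics, rates, init, irr, vis = viscosity_params()) {
  stopifnot(inherits(optics, "pp_optics"), inherits(rates, "pp_rates"),
            inherits(init, "pp_init"), inherits(irr, "pp_irr"),
            inherits(vis, "pp_vis"))
  if (rates$kT <= 0) stop("kT must be positive")
  irr2 <- irr
  if (is.null(irr2$z_grid)) {
    irr2$z_grid <- seq(0, init$H, length.out = max(irr$nz, 1L))
  }
  if (is.null(irr2$t_grid)) {
    irr2$t_grid <- seq(0, irr$t_end, length.out = max(irr$nt, 2L))
  }
  chk_grid(irr2$z_grid, "z_grid", from_zero = TRUE)
  chk_grid(irr2$t_grid, "t_grid", from_zero = TRUE)
  if (max(irr2$z_grid) > init$H + 1e-12) {
    stop("z_grid extends beyond the film thickness H")
  }
  irr2$nz <- length(irr2$z_grid)
  irr2$nt <- length(irr2$t_grid)
  derived <- list(
    K = rates$K,
    A2 = 2.3 * (optics$a_ps * init$C0 + optics$Q),
    A_avg = 1.15 * (optics$a_ps + optics$b_prod) * init$C0 + 2.3 * optics$Q,
    A_floor = 2.3 * (optics$b_prod * init$C0 + optics$Q)
  )
  structure(list(optics = optics, rates = rates, init = init, irr = irr2,
                 vis = vis, derived = derived),
            class = "pp_params")
}

#' @export
print.pp_params <- function(x, ...) {
  cat("<pp_params>\n")
  cat(sprintf("  optics: a_ps=%g b_prod=%g Q=%g b_exc=%g\n",
              x$optics$a_ps, x$optics$b_prod, x$optics$Q, x$optics$b_exc))
  cat(sprintf("  rates : kp=%g kT=%g ki=%g (K=%.6g)\n",
              x$rates$kp, x$rates$kT, x$rates$ki, x$derived$K))
  cat(sprintf("  init  : C0=%g Y0=%g A0=%g H=%g cm P_max=%g\n",
              x$init$C0, x$init$Y0, x$init$A0, x$init$H, x$init$P_max))
  cat(sprintf("  irr   : I0=%g mW/cm2, t_end=%g s, %d z-nodes, %d t-points\n",
              x$irr$I0, x$irr$t_end, length(x$irr$z_grid), length(x$irr$t_grid)))
  cat(sprintf("  vis   : v=%g m=%g enabled=%s\n",
              x$vis$v, x$vis$m, x$vis$enabled))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

#' Convert a parameter bundle to a plain (config) list
#'
#' The list round-trips through JSON: `params_from_list(params_to_list(p))`
#' reproduces `p` exactly.
#'
#' @param p a `pp_params` bundle.
#' @return A nested plain list with sections optics/rates/init/irradiation/
#'   viscosity.
#' @export
params_to_list <- function(p) {
  stopifnot(inherits(p, "pp_params"))
  list(
    optics = p$optics[c("a_ps", "b_prod", "Q", "b_exc")],
    rates = p$rates[setdiff(names(p$rates), "K")],
    init = unclass(p$init)[c("C0", "Y0", "A0", "H", "P_max")],
    irradiation = list(I0 = p$irr$I0, t_end = p$irr$t_end,
                       z_grid = p$irr$z_grid, t_grid = p$irr$t_grid),
    viscosity = list(v = p$vis$v, m = p$vis$m, enabled = p$vis$enabled)
  )
}

#' Rebuild a parameter bundle from a plain (config) list
#'
#' @param x a list as produced by [params_to_list()] or parsed from a JSON
#'   config file; missing fields fall back to constructor defaults.
#' @return A validated `pp_params` bundle.
#' @export
params_from_list <- function(x) {
  grab <- function(section, fn) do.call(fn, as.list(x[[section]] %||% list()))
  validate_params(
    optics = grab("optics", optical_params),
    rates = grab("rates", rate_constants),
    init = grab("init", state_init),
    irr = grab("irradiation", irradiation),
    vis = grab("viscosity", viscosity_params)
  )
}

#' Read a parameter bundle from a JSON config file
#' @param path file path of a JSON document with sections optics, rates,
#'   init, irradiation, viscosity.
#' @return A validated `pp_params`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  params_from_list(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

# ---- internal checks -------------------------------------------------------

#' @noRd
chk_nonneg <- function(vals) {
  bad <- which(!is.finite(vals) | vals < 0)
  if (length(bad)) {
    stop(names(vals)[bad[1]], " must be a finite non-negative number")
  }
  invisible(TRUE)
}

#' @noRd
chk_grid <- function(g, name, from_zero = FALSE) {
  if (length(g) < 1 || any(!is.finite(g))) stop(name, " must be finite")
  if (length(g) > 1 && any(diff(g) <= 0)) {
    stop(name, " not strictly increasing")
  }
  if (from_zero && abs(g[1]) > 1e-15) stop(name, " must start at 0")
  invisible(TRUE)
}
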