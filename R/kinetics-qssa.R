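# Quasi-steady-state reductions. The short-lived species (triplet T,
# radicals R'/R, singlet oxygen X) relax on ns-us scales, so their time
# derivatives are set to zero and solved algebraically in the slow fields
# (C, O2, A). Two ODE tiers result: "reduced3" keeps the type-II channels,
# "simplified" is the three-equation system the figure-level numerics use.

#' Quasi-steady-state partition factors and radical drive
#'
#' `g = k_xm / (k3 O2 + k_xm A + k5)` (triplet partition, 1/mM),
#' `g' = k3 / (k6 + k11 C + k_xm A)` (singlet-oxygen partition; the
#' `"as_printed"` form uses `k_tm A` in the denominator), the radical drive
#' `B = b_exc I C g A` (mM/s) and sink sum `G = ki O2 + 2 k12 R' + kp A`
#' with the decoupled seed `R' = sqrt(B/kT)`. Also returns the
#' quasi-steady triplet `T = b_exc I g C` and singlet oxygen
#' `X = b_exc I C g' O2 / k_xm` (the printed form omits the factor C;
#' `x_form = "as_printed"` reproduces it).
#'
#' @param C,O2,A slow-species concentrations, mM (vectorized).
#' @param I local light intensity, mW/cm2.
#' @param params a `pp_params` bundle (or a `pp_rates` plus `b_exc`).
#' @param g_prime_form `"physical"` (k_xm A sink) or `"as_printed"`
#'   (k_tm A).
#' @param x_form `"with_C"` or `"as_printed"`.
#' @return list with g, g_prime, B, G, T, X, Rp.
#' @export
qssa_factors <- function(C, O2, A, I, params,
                         g_prime_form = c("physical", "as_printed"),
                         x_form = c("with_C", "as_printed")) {
  g_prime_form <- match.arg(g_prime_form)
  x_form <- match.arg(x_form)
  r <- params$rates; b <- params$optics$b_exc
  if (any(C < 0 | O2 < 0 | A < 0)) stop("concentrations must be >= 0")
  den_g <- r$k3 * O2 + r$k_xm * A + r$k5
  if (any(den_g == 0)) stop("degenerate input: g denominator vanishes")
  g <- r$k_xm / den_g
  den_gp <- r$k6 + r$k11 * C +
    (if (g_prime_form == "physical") r$k_xm else r$k_tm) * A
  if (any(den_gp == 0)) stop("degenerate input: g' denominator vanishes")
  g_prime <- r$k3 / den_gp
  B <- b * I * C * g * A
  Rp <- sqrt(pmax(B, 0) / r$kT)
  G <- r$ki * O2 + 2 * r$k12 * Rp + r$kp * A
  Tq <- b * I * g * C
  X <- if (x_form == "with_C") b * I * C * g_prime * O2 / r$k_xm
       else b * I * g_prime * O2 / r$k_xm
  list(g = g, g_prime = g_prime, B = B, G = G, T = Tq, X = X, Rp = Rp)
}

#' Closed-form quasi-steady propagating-radical concentration
#'
#' The positive root of `2 kT R^2 + G R - 2B = 0`:
#' `R = [-G + sqrt(G^2 + 16 kT B)] / (4 kT)`, evaluated in the
#' cancellation-free form `4B / (G + sqrt(G^2 + 16 kT B))`.
#'
#' @param B radical drive, mM/s.
#' @param G sink sum `ki O2 + 2 k12 R' + kp A`, 1/s.
#' @param kT bimolecular termination constant (> 0).
#' @return R in mM (vectorized).
#' @export
radical_closed_form <- function(B, G, kT) {
  if (any(B < 0) || any(G < 0)) stop("B and G must be >= 0")
  if (any(kT <= 0)) stop("kT must be positive")
  quad_pos_root(2 * kT, G, 2 * B)
}

#' Coupled steady-state radical pair by damped Newton iteration
#'
#' Solves the 2x2 steady system for (R', R):
#' `2B - k12 R R' - 2 kT R'^2 = 0` and
#' `2 kT R'^2 - kp A R - k12 R R' - 2 kT R^2 - ki O2 R = 0`,
#' seeded from the decoupled solution `R' = sqrt(B/kT)`.
#'
#' @param B radical drive, mM/s.
#' @param kT,k12,kp,ki rate constants.
#' @param A,O2 monomer and oxygen concentrations, mM.
#' @param tol residual tolerance (relative to `max(B, kT R'^2)`).
#' @param maxit Newton iteration cap.
#' @return list(Rp, R, residual, iterations).
#' @export
radical_pair_numeric <- function(B, kT, k12, kp, A, O2 = 0, ki = 0,
                                 tol = 1e-12, maxit = 100L) {
  if (B < 0) stop("B must be >= 0")
  if (kT <= 0) stop("kT must be positive")
  if (B == 0) return(list(Rp = 0, R = 0, residual = 0, iterations = 0L))
  Rp <- sqrt(B / kT)
  lin <- kp * A + ki * O2
  R <- quad_pos_root(2 * kT, lin + k12 * Rp, 2 * kT * Rp^2)
  fres <- function(Rp, R) {
    c(2 * B - k12 * R * Rp - 2 * kT * Rp^2,
      2 * kT * Rp^2 - lin * R - k12 * R * Rp - 2 * kT * R^2)
  }
  scale <- max(B, kT * Rp^2)
  f <- fres(Rp, R)
  it <- 0L
  while (max(abs(f)) > tol * scale && it < maxit) {
    it <- it + 1L
    Jm <- matrix(c(-k12 * R - 4 * kT * Rp, -k12 * Rp,
                   4 * kT * Rp - k12 * R, -lin - k12 * Rp - 4 * kT * R),
                 2, 2, byrow = TRUE)
    step <- tryCatch(solve(Jm, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      Rp_n <- max(Rp + lambda * step[1], 0)
      R_n <- max(R + lambda * step[2], 0)
      f_n <- fres(Rp_n, R_n)
      if (max(abs(f_n)) < max(abs(f)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    Rp <- Rp_n; R <- R_n; f <- f_n
  }
  if (max(abs(f)) > tol * scale) {
    warning("radical_pair_numeric: residual ", signif(max(abs(f)), 3),
            " after ", it, " iterations (tolerance ",
            signif(tol * scale, 3), ")")
  }
  list(Rp = Rp, R = R, residual = max(abs(f)), iterations = it)
}

#' Weak-inhibition expansion of the radical concentration
#'
#' Valid when the sink term is small against the bimolecular drive
#' (`G^2 << 8 kT B`): `R = sqrt(B/kT) - ki O2 (1 - B') / (4 kT)` with
#' `B' = 0.5 ki O2 / sqrt(8 B kT)`. Warns outside the stated regime and
#' clips a negative result to 0.
#'
#' @param B radical drive, mM/s.
#' @param O2 oxygen concentration, mM.
#' @param ki radical-oxygen inhibition constant.
#' @param kT bimolecular termination constant.
#' @return R in mM (vectorized).
#' @export
radical_weak_inhibition <- function(B, O2, ki, kT) {
  if (any(B < 0) || any(O2 < 0)) stop("B and O2 must be >= 0")
  if (any(kT <= 0)) stop("kT must be positive")
  G <- ki * O2
  if (any(B > 0 & G^2 > 0.5 * 8 * kT * B)) {
    warning("outside the weak-inhibition regime (G^2 not << 8 kT B)")
  }
  Bp <- ifelse(B > 0, 0.5 * G / sqrt(8 * B * kT), 0)
  R <- sqrt(B / kT) - G * (1 - Bp) / (4 * kT)
  if (any(R < 0)) {
    warning("weak-inhibition R clipped at 0")
    R <- pmax(R, 0)
  }
  R
}

#' Saturating oxygen resupply term
#'
#' `P = (1 - O2/Y0) P_max`, floored at 0 when the film is oversaturated.
#'
#' @param O2 current oxygen concentration, mM.
#' @param Y0 saturation (initial) oxygen concentration, mM.
#' @param P_max maximum replenishment rate, mM/s.
#' @return P in mM/s (vectorized).
#' @export
oxygen_supply <- function(O2, Y0, P_max) {
  if (P_max > 0 && Y0 <= 0) stop("P_max > 0 requires Y0 > 0")
  if (P_max == 0) return(rep(0, length(O2)))
  pmax(0, 1 - O2 / Y0) * P_max
}

# ---- reduced ODE tiers -----------------------------------------------------

#' @noRd
qssa_rhs_factory <- function(params, I_nodes, tier, include_RE, viscosity,
                             g_prime_form) {
  r <- params$rates; b <- params$optics$b_exc
  Y0 <- params$init$Y0; A0 <- params$init$A0; P_max <- params$init$P_max
  k_ratio <- if (r$k_xm > 0) r$k11 / r$k_xm else 0
  vis_v <- params$vis$v
  use_vis <- viscosity && params$vis$enabled && vis_v > 0
  function(Y, t) {
    C <- pmax(Y[1, ], 0); O2 <- pmax(Y[2, ], 0); A <- pmax(Y[3, ], 0)
    kp_v <- r$kp; kT_v <- r$kT
    if (use_vis) {
      eff <- pmin(pmax(1 - A / A0, 0), 1 - 1e-12)
      sc <- viscosity_scale(eff, vis_v)
      kp_v <- r$kp * sc$kp
      kT_v <- r$kT * sc$kT
    }
    g <- r$k_xm / (r$k3 * O2 + r$k_xm * A + r$k5)
    B <- b * I_nodes * C * g * A
    Rp <- sqrt(pmax(B, 0) / kT_v)
    G <- r$ki * O2 + 2 * r$k12 * Rp + kp_v * A
    R <- quad_pos_root(2 * kT_v, G, 2 * B)
    P <- if (P_max > 0) pmax(0, 1 - O2 / Y0) * P_max else 0
    if (tier == "simplified") {
      dC <- -b * I_nodes * C
      dO2 <- -r$ki * R * O2 + P
      dA <- -kp_v * R * A
    } else {
      den_gp <- r$k6 + r$k11 * C +
        (if (g_prime_form == "physical") r$k_xm else r$k_tm) * A
      gp <- r$k3 / den_gp
      RE <- if (include_RE) r$ki * R * O2 + 2 * kT_v * R^2 else 0
      dC <- -b * I_nodes * (g * A + k_ratio * g * gp * C * O2) * C + RE
      dO2 <- -(b * I_nodes * C * g + r$ki * R) * O2 + P
      dA <- -(b * I_nodes * g * C * (1 + gp * O2) + kp_v * R) * A
    }
    rbind(dC, dO2, dA)
  }
}

#' Simulate the quasi-steady-state reduced kinetics
#'
#' Method of lines over the depth grid with the light field recomputed from
#' the current PS profile at the start of every output interval (operator
#' splitting, first order in the output step). Within an interval each node
#' is advanced by the adaptive Rosenbrock solver.
#'
#' @param params a validated `pp_params` bundle.
#' @param tier `"simplified"` (dC = -bIC; dO2 = -ki R O2 + P;
#'   dA = -kp R A) or `"reduced3"` (keeps the type-II coupling terms).
#' @param include_RE logical, enable the PS regeneration term
#'   `ki R O2 + 2 kT R^2` in the reduced3 tier (default off, as in the
#'   simplified system).
#' @param viscosity logical, update (kp, kT) from the local conversion each
#'   step via [viscosity_scale()] (defaults to the bundle's `vis$enabled`).
#' @param g_prime_form passed to the singlet-oxygen partition factor.
#' @param rtol,atol solver tolerances.
#' @return A `pp_trajectory` with fields C, O2, A (plus intensity and
#'   efficacy).
#' @export
#' @examples
#' p <- validate_params(optical_params(b_exc = 0.02), rate_constants(),
#'                      state_init(C0 = 0.01),
#'                      irradiation(I0 = 5, t_end = 30, nz = 5, nt = 16))
#' tr <- simulate_qssa(p)
#' round(tr$efficacy[1, 16], 3)
simulate_qssa <- function(params, tier = c("simplified", "reduced3"),
                          include_RE = FALSE, viscosity = NULL,
                          g_prime_form = c("physical", "as_printed"),
                          rtol = 1e-8, atol = 1e-12) {
  tier <- match.arg(tier)
  g_prime_form <- match.arg(g_prime_form)
  stopifnot(inherits(params, "pp_params"))
  viscosity <- viscosity %||% params$vis$enabled
  z <- params$irr$z_grid; tt <- params$irr$t_grid
  nz <- length(z); nt <- length(tt)
  Y <- rbind(C = rep(params$init$C0, nz),
             O2 = rep(params$init$Y0, nz),
             A = rep(params$init$A0, nz))
  refresh <- function(Ycur, tcur) {
    A_dyn <- absorbance(pmin(pmax(Ycur[1, ], 0), params$init$C0 * (1 + 1e-9)),
                        params$optics, params$init$C0)
    I_nodes <- propagate_intensity(A_dyn, params$irr$I0, z)
    qssa_rhs_factory(params, I_nodes, tier, include_RE, viscosity,
                     g_prime_form)
  }
  sol <- ros_solve(refresh(Y, 0), Y, tt, rtol = rtol, atol = atol,
                   refresh = refresh)
  states <- sol$states
  states[states < 0] <- 0
  # stored intensity: recomputed from the stored PS field
  Cmat <- matrix(states[1, , ], nz, nt)
  A_dyn <- absorbance(pmin(Cmat, params$init$C0 * (1 + 1e-9)),
                      params$optics, params$init$C0)
  I <- propagate_intensity(A_dyn, params$irr$I0, z)
  fields <- list(C = Cmat,
                 O2 = matrix(states[2, , ], nz, nt),
                 A = matrix(states[3, , ], nz, nt))
  new_trajectory(tt, z, fields, I, params$init$A0, params$init$Y0,
                 paste0("qssa_", tier), params, sol$diagnostics)
}
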