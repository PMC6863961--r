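# Shared builders for the test suite. Grids are deliberately small: every
# property here is grid-converged well below the asserted tolerances, and
# the whole suite has to stay inside the CI budget.

quick_params <- function(b_exc = 0.02, I0 = 5, t_end = 30, C0 = 0.01,
                         Y0 = 0.001, A0 = 0.02, H = 0.03, P_max = 0,
                         nz = 5, nt = 16, z_grid = NULL, t_grid = NULL,
                         rates = rate_constants(), vis = viscosity_params(),
                         a_ps = 458, b_prod = 0, Q = 0) {
  validate_params(
    optical_params(a_ps = a_ps, b_prod = b_prod, Q = Q, b_exc = b_exc),
    rates,
    state_init(C0 = C0, Y0 = Y0, A0 = A0, H = H, P_max = P_max),
    irradiation(I0 = I0, t_end = t_end, z_grid = z_grid, t_grid = t_grid,
                nz = nz, nt = nt),
    vis
  )
}

# rebuild a bundle with fresh (smaller) grids, optionally overriding fields
with_grids <- function(p, nz = NULL, nt = NULL, t_end = NULL) {
  cfg <- params_to_list(p)
  if (!is.null(t_end)) cfg$irradiation$t_end <- t_end
  cfg$irradiation$t_grid <- NULL
  if (!is.null(nz)) cfg$irradiation$z_grid <- NULL
  p2 <- params_from_list(cfg)
  cfg2 <- params_to_list(p2)
  if (!is.null(nz)) {
    cfg2$irradiation$z_grid <- seq(0, p$init$H, length.out = nz)
  }
  if (!is.null(nt)) {
    cfg2$irradiation$t_grid <- seq(0, cfg$irradiation$t_end,
                                   length.out = nt)
  }
  params_from_list(cfg2)
}

# scale the fast (triplet / singlet-oxygen channel) rates for the
# stiff-limit property; kT and kp are deliberately untouched so that the
# slow (lumped) solution stays fixed while the relaxation times shrink
scale_fast_rates <- function(r, lam) {
  modify_rates(r, k3 = r$k3 * lam, k5 = r$k5 * lam, k6 = r$k6 * lam,
               k_tm = r$k_tm * lam, k_xm = r$k_xm * lam)
}

# first time at which a monotone series crosses a threshold (linear interp)
first_crossing <- function(t, y, thr) {
  hit <- which(y >= thr)
  if (!length(hit)) return(Inf)
  i <- hit[1]
  if (i == 1) return(t[1])
  t[i - 1] + (thr - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}
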