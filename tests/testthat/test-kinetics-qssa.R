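# Quasi-steady-state factors, radical algebra, and the reduced tiers.

test_that("qssa partition factors honor their limits", {
  p <- quick_params()
  # monomer-dominated sink: g -> 1/A
  f <- qssa_factors(C = 0.01, O2 = 0, A = 0.02, I = 5,
                    quick_params(rates = rate_constants(k5 = 0, k3 = 0)))
  expect_equal(f$g, 1 / 0.02, tolerance = 1e-12)
  expect_equal(f$g * 0.02, 1)  # partition bound saturated
  # general case: g A <= 1
  f2 <- qssa_factors(0.01, 0.001, 0.02, 5, p)
  expect_lte(f2$g * 0.02, 1 + 1e-9)
  expect_gte(f2$B, 0)
  expect_gte(f2$G, 0)
  # anoxic limit: no singlet-oxygen production
  f3 <- qssa_factors(0.01, 0, 0.02, 5, p)
  expect_equal(f3$X, 0)
  expect_equal(f3$g, p$rates$k_xm / (p$rates$k_xm * 0.02 + p$rates$k5))
  expect_error(qssa_factors(0.01, 0.001, 0.02, 5,
                            quick_params(rates = rate_constants(
                              k3 = 0, k5 = 0, k_xm = 0))),
               "degenerate")
})

test_that("radical_closed_form solves its quadratic to machine precision", {
  expect_equal(radical_closed_form(1e-3, 0, 3e6), sqrt(1e-3 / 3e6))
  expect_identical(radical_closed_form(0, 5, 3e6), 0)
  set.seed(11)
  for (i in 1:300) {
    B <- 10^stats::runif(1, -9, 0)
    G <- 10^stats::runif(1, -4, 6)
    kT <- 10^stats::runif(1, 1, 8)
    R <- radical_closed_form(B, G, kT)
    resid <- abs(2 * kT * R^2 + G * R - 2 * B)
    expect_lt(resid, 1e-12 * (2 * B + G * R + 1))
  }
})

test_that("radical pair iteration agrees with its decoupled closed forms", {
  # k12 = 0 decouples: Rp exactly sqrt(B/kT), R from its scalar quadratic
  pn <- radical_pair_numeric(B = 1e-3, kT = 3e6, k12 = 0, kp = 1865,
                             A = 0.02, O2 = 1e-3, ki = 2e5)
  expect_equal(pn$Rp, sqrt(1e-3 / 3e6), tolerance = 1e-12)
  G0 <- 1865 * 0.02 + 2e5 * 1e-3
  expect_equal(pn$R, radical_closed_form(3e6 * pn$Rp^2, G0, 3e6),
               tolerance = 1e-10)
  expect_identical(radical_pair_numeric(0, 3e6, 10, 1865, 0.02)$R, 0)
  # residual oracle over a random box
  set.seed(13)
  for (i in 1:100) {
    B <- 10^stats::runif(1, -8, -2); kT <- 10^stats::runif(1, 3, 7)
    k12 <- 10^stats::runif(1, 0, 4); kp <- 10^stats::runif(1, 0, 3.5)
    A <- 10^stats::runif(1, -3, 0); O2 <- 10^stats::runif(1, -5, -3)
    ki <- 10^stats::runif(1, 3, 6)
    pn <- radical_pair_numeric(B, kT, k12, kp, A, O2, ki = ki)
    expect_lt(pn$residual, 1e-10 * max(B, kT * pn$Rp^2))
  }
})

test_that("weak-inhibition expansion matches the closed form to 2nd order", {
  B <- 1e-3; kT <- 3e6
  expect_equal(radical_weak_inhibition(B, 0, 2e5, kT),
               radical_closed_form(B, 0, kT))
  # error scales quadratically in ki O2
  g1 <- 2; g2 <- 1; g3 <- 0.5   # shrinking sink strengths
  errs <- vapply(c(g1, g2, g3), function(gg) {
    abs(radical_weak_inhibition(B, 1e-3 * gg, 1e4, kT) -
          radical_closed_form(B, 1e4 * 1e-3 * gg, kT))
  }, 0)
  expect_equal(errs[1] / errs[2], 4, tolerance = 0.15)
  expect_equal(errs[2] / errs[3], 4, tolerance = 0.15)
  # oxygen inhibition: R decreasing in O2 at fixed drive
  o2 <- seq(0, 2e-3, length.out = 9)
  R <- radical_weak_inhibition(B, o2, 1e4, kT)
  expect_true(all(diff(R) < 0))
  expect_warning(radical_weak_inhibition(1e-9, 1e-3, 1e6, kT),
                 "weak-inhibition")
})

test_that("oxygen resupply saturates linearly", {
  expect_equal(oxygen_supply(0.001, 0.001, 5e-6), 0)
  expect_equal(oxygen_supply(0, 0.001, 5e-6), 5e-6)
  expect_equal(oxygen_supply(5e-4, 0.001, 5e-6), 2.5e-6)
  expect_equal(oxygen_supply(2e-3, 0.001, 5e-6), 0)  # oversaturated: floored
  expect_error(oxygen_supply(0, 0, 5e-6), "Y0")
})

test_that("surface solution matches the oxygen-free closed form to 1e-6", {
  # z = 0, I = I0, no oxygen, negligible linear radical sinks: the
  # simplified tier reduces to dA/dt = -kp sqrt(b I0 C0 e^(-b I0 t)/kT) A
  # whose exponent has the closed form
  # S(t) = K sqrt(b I0 C0) 2 (1 - e^(-b I0 t/2)) / (b I0)
  p <- quick_params(C0 = 0.01, Y0 = 0, A0 = 1e-8,
                    rates = rate_constants(k12 = 0, k5 = 0, ki = 0),
                    z_grid = 0, t_grid = seq(0, 100, 2))
  tr <- simulate_qssa(p, rtol = 1e-10, atol = 1e-16)
  b <- 0.02; I0 <- 5; C0 <- 0.01
  S <- p$derived$K * sqrt(b * I0 * C0) * 2 *
    (1 - exp(-b * I0 * tr$t / 2)) / (b * I0)
  expect_lt(max(abs(tr$efficacy[1, ] - (1 - exp(-S)))), 1e-6)
})

test_that("reduced3 and simplified tiers agree when type-II is off", {
  # k3 = k11 = 0 silences the singlet-oxygen channel (k_xm stays > 0: it
  # doubles as the triplet partition constant); monomer >> PS makes the
  # triplet monomer sink negligible
  r <- rate_constants(k3 = 0, k11 = 0, k5 = 100, ki = 0, k12 = 0)
  p <- quick_params(Y0 = 0, A0 = 2, rates = r, t_end = 120, nz = 5, nt = 13)
  t1 <- simulate_qssa(p, tier = "simplified")
  t2 <- simulate_qssa(p, tier = "reduced3")
  expect_lt(max(abs(t1$efficacy - t2$efficacy)), 0.01)
})

test_that("induction times are finite, shorter at high I0, longer at high Y0", {
  tid <- function(I0, Y0) {
    p <- quick_params(I0 = I0, Y0 = Y0, t_end = 120, z_grid = 0, nt = 241)
    induction_times(simulate_qssa(p))[1]
  }
  t_i <- vapply(c(0.5, 2, 5, 10), tid, 0, Y0 = 0.001)
  expect_true(all(is.finite(t_i)))
  expect_true(all(diff(t_i) < 0))
  t_y <- vapply(c(5e-4, 1e-3, 2e-3), tid, 0, I0 = 5)
  expect_true(all(diff(t_y) > 0))
})

test_that("exponential oxygen closed form tracks the simulated channel", {
  expect_equal(oxygen_exponential(c(0, 1), 1e-3, c(0, 0)), c(1e-3, 1e-3))
  expect_error(oxygen_exponential(c(0, 1), 1e-3, c(1, 0)), "non-decreasing")
  # fig4 drive at the surface: second-order radical with first-order
  # oxygen, scavenging exponent S' = ki int R(2) dt; agreement within 15%
  # while oxygen remains above 10% of Y0 (the pre-induction window)
  p <- quick_params(I0 = 5, t_end = 40, z_grid = 0, t_grid = seq(0, 40, 0.25))
  tr <- simulate_qssa(p)
  r <- p$rates; b <- 0.02; I0 <- 5; C0 <- 0.01; Y0 <- 0.001
  tt <- tr$t
  S1 <- vapply(tt, function(t) {
    integrate(function(u) r$ki * sqrt(0.5 * b * I0 * C0 * exp(-b * I0 * u) /
                                        r$kT), 0, t)$value
  }, 0)
  O1 <- Y0 * exp(-S1)     # first-order oxygen
  B <- b * I0 * C0 * exp(-b * I0 * tt)
  Bp <- pmin(0.5 * r$ki * O1 / sqrt(8 * B * r$kT), 1)
  R2 <- pmax(sqrt(0.5 * B / r$kT) - r$ki * O1 * (1 - Bp) / (4 * r$kT), 0)
  Sp <- photocure:::cumtrapz(tt, r$ki * R2)
  O2an <- oxygen_exponential(tt, Y0, Sp)
  win <- tr$fields$O2[1, ] > 0.1 * Y0
  expect_lt(max(abs(O2an[win] - tr$fields$O2[1, win]) /
                  tr$fields$O2[1, win]), 0.15)
})
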