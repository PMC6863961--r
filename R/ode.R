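# Adaptive L-stable Rosenbrock integrator (ode23s-type, Shampine-Reichelt
# coefficients) for stiff reaction kinetics. The state is a ns x m matrix
# whose columns are independent (depth nodes with the light field frozen),
# so the Jacobian is block diagonal: one numeric Jacobian costs ns RHS
# evaluations regardless of m, and the stage solves are m small ns x ns
# systems. No ODE-solver package ships in this stack, hence this module;
# it is validated against closed forms in the test suite.

ROS_D <- 1 / (2 + sqrt(2))
ROS_E32 <- 6 + sqrt(2)

#' One integration leg from t0 to t1 with dense clipping at t1 only.
#'
#' @param rhs function(Y, t) -> dY/dt, same ns x m shape as Y.
#' @param Y0 initial state matrix (ns x m).
#' @param t0,t1 time interval.
#' @param rtol,atol relative/absolute tolerances (atol in mM).
#' @param h0 initial step suggestion (carried between legs by callers).
#' @param max_steps abort guard.
#' @return list(Y, h, nsteps, nrejected, nrhs)
#' @noRd
ros_leg <- function(rhs, Y0, t0, t1, rtol = 1e-8, atol = 1e-12,
                    h0 = NULL, max_steps = 200000L) {
  ns <- nrow(Y0); m <- ncol(Y0)
  Y <- Y0; t <- t0
  span <- t1 - t0
  if (span <= 0) return(list(Y = Y, h = h0 %||% span, nsteps = 0L,
                             nrejected = 0L, nrhs = 0L))
  F0 <- rhs(Y, t)
  if (any(!is.finite(F0))) {
    bad <- which(!is.finite(F0), arr.ind = TRUE)[1, ]
    stop("non-finite derivative at t = ", t, " (state row ", bad[1],
         ", node ", bad[2], ")")
  }
  h <- min(h0 %||% (span / 100), span)
  nsteps <- 0L; nrej <- 0L; nrhs <- 1L
  Im <- diag(ns)
  while (t < t1 - 1e-13 * (abs(t1) + span)) {
    if (nsteps + nrej > max_steps) {
      stop("ODE solver exceeded ", max_steps, " steps at t = ", t,
           "; consider loosening rtol/atol")
    }
    h <- min(h, t1 - t)
    # block-diagonal numeric Jacobian: perturb one species row across all
    # nodes at once (forward differences)
    del <- sqrt(.Machine$double.eps) * pmax(abs(Y), 1e-10)
    J <- array(0, c(ns, ns, m))
    for (s in seq_len(ns)) {
      Yp <- Y
      Yp[s, ] <- Y[s, ] + del[s, ]
      Fp <- rhs(Yp, t); nrhs <- nrhs + 1L
      J[, s, ] <- (Fp - F0) / rep(del[s, ], each = ns)
    }
    ok <- TRUE
    Wi <- array(0, c(ns, ns, m))
    for (j in seq_len(m)) {
      W <- Im - (h * ROS_D) * J[, , j]
      Wj <- tryCatch(solve(W), error = function(e) NULL)
      if (is.null(Wj) || any(!is.finite(Wj))) { ok <- FALSE; break }
      Wi[, , j] <- Wj
    }
    if (!ok) { h <- h / 4; nrej <- nrej + 1L; next }
    wsolve <- function(V) {
      out <- V
      for (j in seq_len(m)) out[, j] <- Wi[, , j] %*% V[, j]
      out
    }
    k1 <- wsolve(F0)
    F1 <- rhs(Y + 0.5 * h * k1, t + 0.5 * h); nrhs <- nrhs + 1L
    k2 <- wsolve(F1 - k1) + k1
    Ynew <- Y + h * k2
    F2 <- rhs(Ynew, t + h); nrhs <- nrhs + 1L
    k3 <- wsolve(F2 - ROS_E32 * (k2 - F1) - 2 * (k1 - F0))
    sc <- atol + rtol * pmax(abs(Y), abs(Ynew))
    err <- max(abs(h * (k1 - 2 * k2 + k3) / 6) / sc)
    if (is.finite(err) && err <= 1) {
      t <- t + h; Y <- Ynew; F0 <- F2
      nsteps <- nsteps + 1L
    } else {
      nrej <- nrej + 1L
    }
    fac <- if (!is.finite(err)) 0.2 else max(0.2, min(5, 0.8 * err^(-1 / 3)))
    h <- h * fac
    if (h < 1e-14 * span) {
      stop("ODE step size underflow at t = ", t)
    }
  }
  list(Y = Y, h = h, nsteps = nsteps, nrejected = nrej, nrhs = nrhs)
}

#' Integrate over an output grid, returning every grid state.
#'
#' @param rhs function(Y, t) -> dY (ns x m); may be re-closed by callers
#'   between legs (light refresh) via `refresh`.
#' @param Y0 ns x m initial state.
#' @param times strictly increasing output times, times[1] is t0.
#' @param refresh optional function(Y, t) -> rhs used to rebuild the RHS at
#'   the start of every leg (operator splitting for the frozen light field).
#' @return list(states = array ns x m x nt, diagnostics = list(...))
#' @noRd
ros_solve <- function(rhs, Y0, times, rtol = 1e-8, atol = 1e-12,
                      refresh = NULL, max_steps = 200000L) {
  ns <- nrow(Y0); m <- ncol(Y0); nt <- length(times)
  out <- array(NA_real_, c(ns, m, nt))
  out[, , 1] <- Y0
  Y <- Y0
  h <- NULL
  nsteps <- 0L; nrej <- 0L; nrhs <- 0L
  f <- rhs
  for (i in seq_len(nt - 1L)) {
    if (!is.null(refresh)) f <- refresh(Y, times[i])
    leg <- ros_leg(f, Y, times[i], times[i + 1L], rtol = rtol, atol = atol,
                   h0 = h, max_steps = max_steps)
    Y <- leg$Y; h <- leg$h
    nsteps <- nsteps + leg$nsteps; nrej <- nrej + leg$nrejected
    nrhs <- nrhs + leg$nrhs
    out[, , i + 1L] <- Y
  }
  list(states = out,
       diagnostics = list(steps = nsteps, rejected = nrej, rhs_evals = nrhs,
                          rtol = rtol, atol = atol))
}
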