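# Trajectory container shared by every model tier.

#' @noRd
new_trajectory <- function(t, z, fields, I, A0, Y0, tier, params,
                           diagnostics = list()) {
  eff <- 1 - fields$A / A0
  eff[eff < 0] <- 0
  eff[eff > 1] <- 1
  structure(list(t = t, z = z, fields = fields, I = I, efficacy = eff,
                 A0 = A0, Y0 = Y0, tier = tier, params = params,
                 diagnostics = diagnostics),
            class = "pp_trajectory")
}

#' @export
print.pp_trajectory <- function(x, ...) {
  cat("<pp_trajectory> tier=", x$tier, ", ", length(x$z), " depth nodes x ",
      length(x$t), " times\n", sep = "")
  cat(sprintf("  t in [0, %g] s; z in [0, %g] cm\n", max(x$t), max(x$z)))
  cat(sprintf("  surface efficacy at t_end: %.4f\n",
              x$efficacy[1, length(x$t)]))
  invisible(x)
}

#' Long-format data frame of a trajectory
#'
#' @param x a `pp_trajectory`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `z_cm`, `t_s`, one column per stored
#'   species, `I_mW_cm2`, and `efficacy`.
#' @export
as.data.frame.pp_trajectory <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  nz <- length(x$z); nt <- length(x$t)
  out <- data.frame(z_cm = rep(x$z, nt), t_s = rep(x$t, each = nz))
  for (nm in names(x$fields)) out[[nm]] <- as.vector(x$fields[[nm]])
  out$I_mW_cm2 <- as.vector(x$I)
  out$efficacy <- as.vector(x$efficacy)
  out
}

#' Write a trajectory as CSV (12 significant digits, fixed column order)
#' @param traj a `pp_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], sig12)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Oxygen-depletion induction time per depth node
#'
#' The induction time is recorded when dissolved oxygen first crosses
#' `eps * Y0` (linear interpolation between stored times); the ODE tail
#' only reaches zero asymptotically, hence the epsilon convention.
#'
#' @param traj a `pp_trajectory` with an `O2` field.
#' @param eps crossing fraction of the initial oxygen (default 1e-6).
#' @return Numeric vector over depth nodes; 0 when `Y0 = 0`, `Inf` when the
#'   threshold is never reached within the stored window.
#' @export
induction_times <- function(traj, eps = 1e-6) {
  stopifnot(inherits(traj, "pp_trajectory"))
  if (is.null(traj$fields$O2)) stop("trajectory has no oxygen field")
  Y0 <- traj$Y0
  if (Y0 <= 0) return(rep(0, length(traj$z)))
  thr <- eps * Y0
  apply(traj$fields$O2, 1, function(o2) {
    below <- which(o2 <= thr)
    if (!length(below)) return(Inf)
    i <- below[1]
    if (i == 1L) return(traj$t[1])
    # linear interpolation on the bracketing interval
    t0 <- traj$t[i - 1L]; t1 <- traj$t[i]
    o0 <- o2[i - 1L]; o1 <- o2[i]
    if (o0 == o1) t1 else t0 + (o0 - thr) / (o0 - o1) * (t1 - t0)
  })
}

#' Run summary of a trajectory
#' @param traj a `pp_trajectory`.
#' @return list with final efficacy per depth, induction times per depth
#'   (when oxygen is tracked), tier and solver diagnostics.
#' @export
trajectory_summary <- function(traj) {
  stopifnot(inherits(traj, "pp_trajectory"))
  list(
    tier = traj$tier,
    z_cm = traj$z,
    final_efficacy = traj$efficacy[, length(traj$t)],
    induction_time_s = if (!is.null(traj$fields$O2))
      induction_times(traj) else NULL,
    diagnostics = traj$diagnostics
  )
}
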