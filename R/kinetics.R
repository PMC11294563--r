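#' @title Transition-state kinetics of membrane/cytoplasm exchange
#' @description Concentration-dependent on/off rates derived from the
#'   equilibrium chemical potentials by transition-state theory, calibration
#'   of the kinetic pre-factor from a measured off-rate, and ODE simulation
#'   of the redistribution that follows symmetry breaking (the opening of the
#'   plasma-membrane compartment), including the kinetic-trapping metrics.
#' @name kinetics
NULL

#' Concentration-dependent exchange rates
#'
#' `k_on = lambda / sqrt(D(c_c))`, `k_off_m = lambda * kd_mem / sqrt(D(c_m))`,
#' `k_off_n = lambda * kd_int / sqrt(D(c_n))`, with `D` the crowding factor
#' of [dimer_D()]. Off-rates fall with membrane concentration (dimer
#' stabilization of the bound state). At the thermodynamic equilibrium state
#' these rates satisfy detailed balance exactly:
#' `k_on * c_c = k_off_m * c_m`.
#'
#' @param c_c,c_m,c_n Compartment concentrations, molar (`c_n` may be `NA`
#'   for a two-compartment system).
#' @param params A [model_params()] object (supplies `kd_dim`, `kd_mem`,
#'   `kd_int`).
#' @param lambda_tilde Kinetic pre-factor, M/s. No default: the calibrated
#'   value and the simulation value differ (see [lambda_presets()]).
#' @return A list of class `"rate_set"`: `k_on`, `k_off_m`, `k_off_n` (1/s)
#'   and `lambda_tilde`.
#' @export
exchange_rates <- function(c_c, c_m, c_n = NA_real_, params, lambda_tilde) {
  stopifnot(c_c >= 0, c_m >= 0, lambda_tilde > 0)
  K <- params$kd_dim
  k_on <- lambda_tilde / sqrt(dimer_D(c_c, K))
  k_off_m <- lambda_tilde * params$kd_mem / sqrt(dimer_D(c_m, K))
  k_off_n <- if (!is.na(c_n)) {
    lambda_tilde * params$kd_int / sqrt(dimer_D(c_n, K))
  } else NA_real_
  structure(list(k_on = k_on, k_off_m = k_off_m, k_off_n = k_off_n,
                 lambda_tilde = lambda_tilde),
            class = "rate_set")
}

#' Calibrate the kinetic pre-factor from a measured off-rate
#'
#' Inverts the off-rate expression at an observed membrane unbinding rate:
#' `lambda = k_off_obs * sqrt(D(c_m_obs)) / kd_mem`. Feeding the result back
#' into [exchange_rates()] reproduces `k_off_obs` exactly.
#'
#' @param k_off_obs Observed plasma-membrane unbinding rate, 1/s (e.g. the
#'   FRAP-derived 0.0073 1/s for PAR-2 in polarized cells).
#' @param c_m_obs Membrane slab concentration at which it was measured, molar.
#' @param kd_dim Dimer dissociation constant, molar.
#' @param kd_mem Dimensionless membrane partition constant.
#' @return `lambda_tilde` in M/s.
#' @examples
#' calibrate_lambda(0.0073, 47.6e-6, 358e-9, 10^-2.43) # ~46 M/s
#' @export
calibrate_lambda <- function(k_off_obs, c_m_obs, kd_dim, kd_mem) {
  stopifnot(k_off_obs > 0, c_m_obs > 0, kd_dim > 0)
  if (kd_mem <= 0) stop("kd_mem must be positive")
  k_off_obs * sqrt(dimer_D(c_m_obs, kd_dim)) / kd_mem
}

#' Kinetic pre-factor presets
#'
#' Two reference values for the pre-factor: `calibrated` (46.4 M/s, obtained
#' by [calibrate_lambda()] from the measured off-rate) and `figure5`
#' (4 M/s, the value used for the symmetry-breaking simulations).
#'
#' @param name `"calibrated"` or `"figure5"`.
#' @return lambda_tilde in M/s.
#' @export
lambda_presets <- function(name = c("calibrated", "figure5")) {
  switch(match.arg(name), calibrated = 46.4, figure5 = 4)
}

#' Simulate redistribution after symmetry breaking
#'
#' Integrates the three-compartment exchange ODEs
#' \deqn{dc_c/dt = a[\psi(-k_{on} c_c + k_{off,m} c_m) +
#'       \phi(-k_{on} c_c + k_{off,n} c_n)]}
#' \deqn{dc_m/dt = k_{on} c_c - k_{off,m} c_m, \quad
#'       dc_n/dt = k_{on} c_c - k_{off,n} c_n}
#' from the pre-symmetry-breaking equilibrium (`params_pre`, typically
#' `kd_mem = 1`, i.e. no plasma-membrane preference while the membrane is
#' blocked) under the post-symmetry-breaking parameters (`params_post`,
#' reduced `kd_mem`). The trajectory converges to the `params_post`
#' equilibrium; with strong dimerization this approach is dramatically slowed
#' (kinetic trapping on internal membranes).
#'
#' @param params_pre,params_post [model_params()] objects differing only in
#'   `kd_mem`; both must define `kd_int` and `phi`.
#' @param lambda_tilde Kinetic pre-factor, M/s.
#' @param t_end Final time, seconds (default 1e7 s; integration stops early
#'   once the state is within relative distance 1e-6 of the target
#'   equilibrium).
#' @param n_times Number of log-spaced output times (plus t = 0).
#' @return An object of class `"kinetic_trajectory"`: data frame `ts` with
#'   columns `t`, `c_c`, `c_m`, `c_n`, `f_cyt`, `f_pm`, `f_im`; plus the
#'   target equilibrium state/fractions and the relative gap at the last
#'   computed time.
#' @export
simulate_symmetry_breaking <- function(params_pre, params_post, lambda_tilde,
                                       t_end = 1e7, n_times = 400) {
  stopifnot(inherits(params_pre, "model_params"),
            inherits(params_post, "model_params"),
            isTRUE(all.equal(params_pre$kd_dim, params_post$kd_dim)),
            isTRUE(all.equal(params_pre$c_tot, params_post$c_tot)))
  s0 <- solve_equilibrium(params_pre, 3)
  target <- solve_equilibrium(params_post, 3)
  tgt <- c(target$c_c, target$c_m, target$c_n)

  p <- params_post
  deriv <- function(t, y, parms) {
    r <- exchange_rates(y[1], y[2], y[3], p, lambda_tilde)
    jm <- r$k_on * y[1] - r$k_off_m * y[2]
    jn <- r$k_on * y[1] - r$k_off_n * y[3]
    list(c(-p$a * (p$psi * jm + p$phi * jn), jm, jn))
  }
  # stop early when within 1e-6 relative of the target equilibrium
  root <- function(t, y, parms) max(abs(y - tgt) / tgt) - 1e-6

  times <- c(0, 10^seq(log10(max(t_end * 1e-6, 1e-3)), log10(t_end),
                       length.out = n_times))
  y0 <- c(s0$c_c, s0$c_m, s0$c_n)
  sol <- deSolve::lsodar(y = y0, times = times, func = deriv, parms = NULL,
                         rootfunc = root, rtol = 1e-8, atol = 1e-15)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf(
      "ODE integration failed (istate = %d); the system may be too stiff for t_end = %g s",
      attr(sol, "istate")[1], t_end))
  }
  ts <- as.data.frame(unclass(sol))
  names(ts) <- c("t", "c_c", "c_m", "c_n")
  amt_m <- p$a * p$psi * ts$c_m
  amt_n <- p$a * p$phi * ts$c_n
  tot <- ts$c_c + amt_m + amt_n
  ts$f_cyt <- ts$c_c / tot
  ts$f_pm <- amt_m / tot
  ts$f_im <- amt_n / tot
  last <- nrow(ts)
  structure(
    list(ts = ts, params = p, lambda_tilde = lambda_tilde,
         target = target,
         target_fractions = compartment_fractions(target, p),
         final_rel_gap = max(abs(unlist(ts[last, c("c_c", "c_m", "c_n")]) - tgt) / tgt)),
    class = "kinetic_trajectory"
  )
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  cat(sprintf(
    "Kinetic trajectory: %d time points to t = %.3g s (gap to equilibrium %.2g)\n",
    nrow(x$ts), max(x$ts$t), x$final_rel_gap))
  invisible(x)
}

#' Compartment fractions at a queried time
#'
#' Log-linear interpolation of the trajectory at `t_query`.
#'
#' @param traj A [simulate_symmetry_breaking()] trajectory.
#' @param t_query Time in seconds (must not exceed the last computed time
#'   unless the trajectory already reached equilibrium, in which case the
#'   equilibrium fractions are returned).
#' @return A list `f_cyt`, `f_pm`, `f_im`, `pm_im_ratio`.
#' @export
snapshot_metrics <- function(traj, t_query) {
  ts <- traj$ts
  if (t_query > max(ts$t)) {
    if (traj$final_rel_gap < 1e-5) return(traj$target_fractions)
    stop("t_query beyond computed trajectory that has not yet equilibrated")
  }
  g <- function(col) stats::approx(ts$t, ts[[col]], xout = t_query)$y
  f <- c(g("f_cyt"), g("f_pm"), g("f_im"))
  f <- f / sum(f)
  list(f_cyt = f[1], f_pm = f[2], f_im = f[3], pm_im_ratio = f[2] / f[3])
}

#' Time to reach a fraction of equilibrium plasma-membrane loading
#'
#' First time at which `f_pm(t)` reaches `q` times the equilibrium `f_pm`.
#' Strong dimerization (small `kd_dim`) increases this time -- the
#' memory/responsiveness tradeoff.
#'
#' @param traj A [simulate_symmetry_breaking()] trajectory.
#' @param q Fraction in (0, 1).
#' @return Time in seconds, or `NA` with attribute `reached = FALSE` if the
#'   level is not attained within the computed trajectory.
#' @export
time_to_fraction <- function(traj, q) {
  stopifnot(q > 0, q < 1)
  thr <- q * traj$target_fractions$f_pm
  ts <- traj$ts
  idx <- which(ts$f_pm >= thr)
  if (!length(idx)) {
    return(structure(NA_real_, reached = FALSE))
  }
  i <- idx[1]
  if (i == 1) return(structure(ts$t[1], reached = TRUE))
  # linear interpolation between bracketing points
  t0 <- ts$t[i - 1]; t1 <- ts$t[i]
  f0 <- ts$f_pm[i - 1]; f1 <- ts$f_pm[i]
  structure(t0 + (thr - f0) / (f1 - f0) * (t1 - t0), reached = TRUE)
}
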