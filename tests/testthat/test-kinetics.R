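kd_mem <- 10^-2.43

test_that("exchange rates have the right symmetries and limits", {
  p <- model_params(358e-9, kd_mem, 27e-9, psi = 0.087e6,
                    kd_int = kd_mem, phi = 0.087e6)
  # equal concentrations and equal partition constants: equal off-rates
  r <- exchange_rates(1e-8, 1e-8, 1e-8, p, 4)
  expect_equal(r$k_off_m, r$k_off_n, tolerance = 1e-12)

  # monomer limit: off/on ratio is exactly kd_mem at any concentrations
  p_mono <- model_params(1e3, kd_mem, 27e-9, psi = 0.087e6,
                         kd_int = 5 * kd_mem, phi = 0.087e6)
  r2 <- exchange_rates(1e-8, 5e-5, 1e-6, p_mono, 4)
  expect_equal(r2$k_off_m / r2$k_on, kd_mem, tolerance = 1e-6)

  # off-rate decreases with membrane concentration (dimer stabilization)
  ks <- vapply(c(1e-8, 1e-6, 1e-4), function(cm) {
    exchange_rates(1e-8, cm, NA, model_params(358e-9, kd_mem, 27e-9), 4)$k_off_m
  }, numeric(1))
  expect_true(all(diff(ks) < 0))

  # the printed calibration round-trips through the rate expression
  lam <- calibrate_lambda(0.0073, 47.6e-6, 358e-9, kd_mem)
  r3 <- exchange_rates(1e-8, 47.6e-6, NA, model_params(358e-9, kd_mem, 27e-9),
                       lam)
  expect_equal(r3$k_off_m, 0.0073, tolerance = 1e-12)
})

test_that("pre-factor calibration matches its closed form and is linear", {
  lam <- calibrate_lambda(0.0073, 47.6e-6, 358e-9, kd_mem)
  expect_equal(lam, 0.0073 * sqrt(dimer_D(47.6e-6, 358e-9)) / kd_mem,
               tolerance = 1e-12)
  expect_equal(calibrate_lambda(2 * 0.0073, 47.6e-6, 358e-9, kd_mem),
               2 * lam, tolerance = 1e-12)
  # monomer limit: sqrt(2) factor from D(0) = 2
  expect_equal(calibrate_lambda(0.01, 1e-9, 1e3, 0.1),
               0.01 * sqrt(2) / 0.1, tolerance = 1e-6)
  expect_error(calibrate_lambda(0.0073, 47.6e-6, 358e-9, 0), "positive")
})

test_that("detailed balance holds at thermodynamic equilibrium", {
  set.seed(11)
  for (i in 1:1000) {
    km <- 10^runif(1, -4, -1)
    p <- model_params(
      kd_dim = 10^runif(1, -9, -4), kd_mem = km,
      c_tot = 10^runif(1, -10, -7), psi = 0.087e6,
      kd_int = km * 10^runif(1, 0, 1), phi = 0.087e6
    )
    s <- solve_equilibrium(p, 3)
    r <- exchange_rates(s$c_c, s$c_m, s$c_n, p, lambda_tilde = 4)
    expect_equal(r$k_off_m * s$c_m / (r$k_on * s$c_c), 1, tolerance = 1e-10)
    expect_equal(r$k_off_n * s$c_n / (r$k_on * s$c_c), 1, tolerance = 1e-10)
  }
})

mk3 <- function(kd_dim, km, psi = 0.087e6) {
  model_params(kd_dim, km, 27e-9, psi = psi,
               kd_int = 5 * kd_mem, phi = psi)
}

test_that("symmetry breaking trajectory conserves mass and reaches the target equilibrium", {
  traj <- simulate_symmetry_breaking(mk3(358e-9, 1), mk3(358e-9, kd_mem),
                                     lambda_tilde = 4, t_end = 1e6)
  p <- traj$params
  tot <- traj$ts$c_c + p$a * (p$psi * traj$ts$c_m + p$phi * traj$ts$c_n)
  expect_equal(tot / 27e-9, rep(1, nrow(traj$ts)), tolerance = 1e-7)
  expect_true(all(traj$ts[c("c_c", "c_m", "c_n")] >= 0))
  expect_lt(traj$final_rel_gap, 1e-5)
  # endpoint against the independent equilibrium solve
  eq <- solve_equilibrium(mk3(358e-9, kd_mem), 3)
  n <- nrow(traj$ts)
  expect_equal(traj$ts$c_m[n], eq$c_m, tolerance = 1e-4)
})

test_that("identical pre/post parameters give a constant trajectory", {
  traj <- simulate_symmetry_breaking(mk3(358e-9, kd_mem), mk3(358e-9, kd_mem),
                                     lambda_tilde = 4, t_end = 1e4)
  expect_equal(max(traj$ts$c_m) / min(traj$ts$c_m), 1, tolerance = 1e-6)
  expect_equal(max(traj$ts$c_c) / min(traj$ts$c_c), 1, tolerance = 1e-6)
})

test_that("doubling the pre-factor halves the timescale exactly", {
  t1 <- simulate_symmetry_breaking(mk3(358e-9, 1), mk3(358e-9, kd_mem),
                                   lambda_tilde = 4, t_end = 2000,
                                   n_times = 100)
  t2 <- simulate_symmetry_breaking(mk3(358e-9, 1), mk3(358e-9, kd_mem),
                                   lambda_tilde = 8, t_end = 1000,
                                   n_times = 100)
  s1 <- snapshot_metrics(t1, 800)
  s2 <- snapshot_metrics(t2, 400)
  expect_equal(s1$f_pm, s2$f_pm, tolerance = 1e-5)
  expect_equal(s1$f_im, s2$f_im, tolerance = 1e-5)
})

test_that("stronger dimerization slows plasma-membrane loading monotonically", {
  kds <- c(3.58e-6, 3.58e-7, 3.58e-8) # weak to strong dimerization
  t50 <- vapply(kds, function(kd) {
    traj <- simulate_symmetry_breaking(mk3(kd, 1), mk3(kd, kd_mem),
                                       lambda_tilde = 4, t_end = 1e6)
    as.numeric(time_to_fraction(traj, 0.5))
  }, numeric(1))
  expect_true(all(diff(t50) > 0))
})

test_that("snapshot metrics interpolate fractions that sum to one", {
  traj <- simulate_symmetry_breaking(mk3(3.58e-9, 1), mk3(3.58e-9, kd_mem),
                                     lambda_tilde = 4, t_end = 1e6)
  s <- snapshot_metrics(traj, 600)
  expect_equal(s$f_cyt + s$f_pm + s$f_im, 1, tolerance = 1e-12)
  # t = 0: the pre-symmetry-breaking state, PM fraction small (kd_mem = 1)
  s0 <- snapshot_metrics(traj, 0)
  expect_lt(s0$f_pm, 0.01)
  # strong dimer at NEBD time: internal membranes still dominate the PM
  # even though the equilibrium strongly prefers the PM (kinetic trapping)
  expect_gt(s$f_im, s$f_pm)
  expect_gt(traj$target_fractions$f_pm, traj$target_fractions$f_im)
  # level never reached within a short horizon reports a sentinel
  short <- simulate_symmetry_breaking(mk3(3.58e-9, 1), mk3(3.58e-9, kd_mem),
                                      lambda_tilde = 4, t_end = 100)
  tt <- time_to_fraction(short, 0.99)
  expect_true(is.na(tt))
  expect_false(attr(tt, "reached"))
})
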