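test_that("dimer partition satisfies mass action and conservation", {
  # c = K forces equal split (sqrt(9) = 3)
  p <- dimer_partition(358e-9, 358e-9)
  expect_equal(p$c1, 179e-9, tolerance = 1e-12)
  expect_equal(p$c2, 179e-9, tolerance = 1e-12)

  # dilute limit: all monomer
  p <- dimer_partition(1e-15, 358e-9)
  expect_equal(p$c1, 1e-15, tolerance = 1e-6)
  expect_lt(p$c2 / 1e-15, 1e-5)

  # concentrated regime against the bisection oracle
  c <- 81.2e-6
  K <- 358e-9
  p <- dimer_partition(c, K)
  c1_oracle <- oracle_monomer(c, K)
  expect_equal(p$c1, c1_oracle, tolerance = 1e-10)
  expect_equal(p$c2 / c, 0.95, tolerance = 0.01) # ~95% dimer by mass

  # invariants across a random sweep
  set.seed(1)
  for (i in 1:50) {
    c <- 10^runif(1, -12, -3)
    K <- 10^runif(1, -9, -3)
    p <- dimer_partition(c, K)
    expect_equal(p$c1 + p$c2, c, tolerance = 1e-12)
    if (p$c2 > 1e-30) {
      expect_equal(p$c1^2 / (p$c2 / 2), K, tolerance = 1e-9)
    }
  }
  expect_error(dimer_partition(-1e-9, 358e-9), "nonnegative")
})

test_that("reduced activity is the monomer concentration with the right limits", {
  K <- 358e-9
  cs <- 10^seq(-12, -3, length.out = 40)
  act <- reduced_activity(cs, K)
  # identity with c * sqrt(2 / D(c))
  expect_equal(act, cs * sqrt(2 / dimer_D(cs, K)), tolerance = 1e-12)
  # strictly increasing
  expect_true(all(diff(act) > 0))
  # monomer limit: equals c
  expect_equal(reduced_activity(10e-9, 1), 10e-9, tolerance = 1e-6)
  expect_equal(reduced_activity(0, K), 0)
  # dimer-dominated asymptote sqrt(c * K / 2)
  c_big <- 1e-2
  expect_equal(reduced_activity(c_big, K) / sqrt(c_big * K / 2), 1,
               tolerance = 1e-2)
  # inverse round-trip
  expect_equal(activity_to_conc(act, K), cs, tolerance = 1e-10)
})

test_that("equilibrium solver matches the monomer-limit closed form", {
  p <- model_params(kd_dim = 1, kd_mem = 10^-2.43, c_tot = 27e-9)
  s <- solve_equilibrium(p)
  a_psi <- p$a * p$psi
  c_c_expected <- 27e-9 / (1 + a_psi / p$kd_mem)
  # kd_dim = 1 M leaves a ~1e-5 residual dimer correction at c_m ~ 6 uM
  expect_equal(s$c_c, c_c_expected, tolerance = 1e-4)
  expect_equal(s$c_m, c_c_expected / p$kd_mem, tolerance = 1e-4)
  expect_equal(s$c_c, 21.9e-9, tolerance = 0.005)
  expect_equal(s$c_m, 5.9e-6, tolerance = 0.005)

  # no membrane preference, thin slab: everything stays cytoplasmic
  p2 <- model_params(kd_dim = 425e-9, kd_mem = 1, c_tot = 27e-9)
  s2 <- solve_equilibrium(p2)
  expect_equal(s2$c_m, s2$c_c, tolerance = 1e-8)
  expect_equal(s2$c_c, 27e-9, tolerance = 1e-3)

  # monomer-limit partition ratio for huge kd_dim
  p3 <- model_params(kd_dim = 1e3, kd_mem = 10^-2, c_tot = 10e-9)
  s3 <- solve_equilibrium(p3)
  expect_equal(s3$c_m / s3$c_c, 1 / p3$kd_mem, tolerance = 1e-4)

  # degenerate input
  s0 <- solve_equilibrium(model_params(425e-9, 10^-2.43, 0))
  expect_equal(s0$c_c, 0)
  expect_equal(s0$c_m, 0)
})

test_that("solver agrees with brute-force chemical-potential bisection", {
  set.seed(7)
  for (i in 1:20) {
    kd_dim <- 10^runif(1, -8, -4)
    kd_mem <- 10^runif(1, -4, -1)
    c_tot <- 10^runif(1, -10, -7)
    s <- solve_equilibrium(model_params(kd_dim, kd_mem, c_tot))
    o <- oracle_equilibrium(kd_dim, kd_mem, c_tot)
    expect_equal(s$c_c, o$c_c, tolerance = 1e-8)
    expect_equal(s$c_m, o$c_m, tolerance = 1e-8)
  }
})

test_that("conservation and mass-action invariants hold over random parameter draws", {
  set.seed(42)
  n_draws <- 1000
  for (i in seq_len(n_draws)) {
    three <- i %% 2 == 0
    kd_mem <- 10^runif(1, -4, 0)
    p <- model_params(
      kd_dim = 10^runif(1, -9, -3), kd_mem = kd_mem,
      c_tot = 10^runif(1, -11, -6),
      psi = 10^runif(1, 4.5, 5.5) * 1,
      kd_int = if (three) kd_mem * 10^runif(1, 0, 1.5) else NA_real_,
      phi = if (three) 10^runif(1, 4.5, 5.5) else NA_real_
    )
    s <- solve_equilibrium(p, if (three) 3 else 2)
    bound <- p$a * (p$psi * s$c_m + if (three) p$phi * s$c_n else 0)
    expect_equal(s$c_c + bound, p$c_tot, tolerance = 1e-9)
    # per-compartment mass action and exact totals
    tot <- c(s$c_c, s$c_m, if (three) s$c_n)
    expect_equal(unname(s$c1 + s$c2), tot, tolerance = 1e-12)
    ok <- s$c2 > 1e-30
    expect_equal(unname(s$c1[ok]^2 / (s$c2[ok] / 2)),
                 rep(p$kd_dim, sum(ok)), tolerance = 1e-9)
    # chemical-potential equality via activities
    expect_equal(reduced_activity(s$c_c, p$kd_dim),
                 p$kd_mem * reduced_activity(s$c_m, p$kd_dim),
                 tolerance = 1e-9)
    if (three) {
      expect_equal(reduced_activity(s$c_c, p$kd_dim),
                   p$kd_int * reduced_activity(s$c_n, p$kd_dim),
                   tolerance = 1e-9)
    }
  }
})

test_that("compartment fractions behave as the three-compartment model predicts", {
  kd_mem <- 10^-2.43
  mk <- function(kd_dim, kd_int = 5 * kd_mem) {
    model_params(kd_dim, kd_mem, 27e-9, psi = 0.087e6,
                 kd_int = kd_int, phi = 0.087e6)
  }
  # symmetric compartments: ratio exactly 1
  p_sym <- mk(425e-9, kd_int = kd_mem)
  f_sym <- compartment_fractions(solve_equilibrium(p_sym, 3), p_sym)
  expect_equal(f_sym$pm_im_ratio, 1, tolerance = 1e-9)
  expect_equal(f_sym$f_cyt + f_sym$f_pm + f_sym$f_im, 1, tolerance = 1e-12)

  # weaker internal binding: PM preferred
  p <- mk(425e-9)
  f <- compartment_fractions(solve_equilibrium(p, 3), p)
  expect_gt(f$pm_im_ratio, 1)

  # stronger dimerization never decreases the PM:IM preference
  ratios <- vapply(c(1e-5, 1e-6, 1e-7, 1e-8, 1e-9), function(kd) {
    pk <- mk(kd)
    compartment_fractions(solve_equilibrium(pk, 3), pk)$pm_im_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) >= -1e-9))

  # dilute monomer limit: amount ratio tends to kd_int / kd_mem = 5
  p_dil <- model_params(1, kd_mem, 1e-12, psi = 0.087e6,
                        kd_int = 5 * kd_mem, phi = 0.087e6)
  f_dil <- compartment_fractions(solve_equilibrium(p_dil, 3), p_dil)
  expect_equal(f_dil$pm_im_ratio, 5, tolerance = 1e-4)
})

test_that("cooperativity landscape is bounded, linear in the limits, unimodal in between", {
  # dimerization far off on either side: slope 1
  expect_equal(score_model(1, 10^-2.43), 1, tolerance = 1e-3)
  expect_equal(score_model(1e-15, 10^-2.43), 1, tolerance = 5e-3)

  kd_dim_grid <- 10^seq(-10, -3, length.out = 8)
  kd_mem_grid <- c(10^-3, 10^-2.43, 10^-2)
  land <- cooperativity_landscape(kd_dim_grid, kd_mem_grid)
  expect_true(all(land >= 1 - 1e-3))
  expect_true(all(land <= 2 + 1e-3))
  for (j in seq_along(kd_mem_grid)) {
    col <- land[, j]
    peak <- which.max(col)
    expect_gt(peak, 1)
    expect_lt(peak, length(col))
    # rises to the peak then falls: unimodal columns
    expect_true(all(diff(col[seq_len(peak)]) > -1e-6))
    expect_true(all(diff(col[peak:length(col)]) < 1e-6))
  }
  # strong membrane binding at intermediate dimer affinity: alpha > 1.5
  expect_gt(max(land[, 1]), 1.5)
})
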