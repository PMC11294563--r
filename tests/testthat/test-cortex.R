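test_that("forward model is an exact tensor-product sum", {
  prof <- initial_profiles(50)
  L <- 30
  # membrane term off: all columns identical
  img <- simulate_cortex_image(2, rep(0, L), prof)
  expect_equal(img, 2 * prof$s_cyt %o% rep(1, L))
  expect_true(all(apply(img, 1, function(r) diff(range(r))) == 0))
  # cytoplasm off, uniform membrane: rank 1
  img2 <- simulate_cortex_image(0, rep(3, L), prof)
  expect_equal(qr(img2)$rank, 1)
  # linearity
  cm <- runif(L)
  expect_equal(simulate_cortex_image(2 * 1.5, 2 * cm, prof),
               2 * simulate_cortex_image(1.5, cm, prof), tolerance = 1e-12)
})

test_that("quantification round-trips the forward model exactly (property)", {
  prof <- initial_profiles(50, centre = 24, width = 2.5)
  set.seed(8)
  for (i in 1:200) {
    L <- sample(20:60, 1)
    c_cyt <- runif(1, 0.1, 10)
    c_mem <- runif(L, 0, 5)
    img <- simulate_cortex_image(c_cyt, c_mem, prof)
    q <- quantify_image(img, prof)
    expect_equal(q$c_cyt, c_cyt, tolerance = 1e-8)
    expect_equal(q$c_mem, c_mem, tolerance = 1e-8)
    expect_lt(q$loss, 1e-16)
  }
})

test_that("gradient-descent quantification agrees with closed-form least squares", {
  prof <- initial_profiles(50)
  set.seed(9)
  img <- simulate_cortex_image(2, runif(40, 0, 3), prof, noise_sd = 0.05)
  q_lsq <- quantify_image(img, prof)
  q_gd <- quantify_image(img, prof, method = "adam")
  expect_equal(q_gd$c_cyt, q_lsq$c_cyt, tolerance = 1e-6)
  expect_equal(q_gd$c_mem, q_lsq$c_mem, tolerance = 1e-6)
})

test_that("pure-cytoplasm images quantify with near-zero membrane signal", {
  prof <- initial_profiles(50)
  img <- simulate_cortex_image(3, rep(0, 25), prof)
  q <- quantify_image(img, prof)
  expect_equal(q$c_cyt, 3, tolerance = 1e-8)
  expect_lt(max(abs(q$c_mem)), 1e-8)
})

test_that("cytoplasmic profile training recovers the generating profile", {
  truth <- initial_profiles(50, centre = 26.5, width = 3)
  gen <- gen_cortex_images(n_cyt = 4, n_pol = 2, L = 50, profiles = truth,
                           noise_sd = 0, seed = 11)
  fit <- train_cyt_profile(gen$cyt_images)
  expect_lt(sqrt(mean((fit$s_cyt - truth$s_cyt)^2)), 1e-3)
  expect_equal(fit$c_cyt, gen$truth$c_cyt_cyt, tolerance = 1e-6)
  # plateau normalization convention
  expect_equal(mean(fit$s_cyt[46:50]), 1, tolerance = 1e-12)

  # per-image gain invariance: scaled image changes only its own estimate
  imgs <- gen$cyt_images
  imgs[[2]] <- imgs[[2]] * 3
  fit2 <- train_cyt_profile(imgs)
  expect_lt(sqrt(mean((fit2$s_cyt - fit$s_cyt)^2)), 1e-5)
  expect_equal(fit2$c_cyt[2] / fit$c_cyt[2], 3, tolerance = 1e-4)
  expect_equal(fit2$c_cyt[1], fit$c_cyt[1], tolerance = 1e-4)

  # 1%-of-plateau noise keeps the profile within 1%
  genN <- gen_cortex_images(n_cyt = 6, n_pol = 2, L = 50, profiles = truth,
                            noise_sd = 0.02, seed = 12)
  fitN <- train_cyt_profile(genN$cyt_images)
  expect_lt(sqrt(mean((fitN$s_cyt - truth$s_cyt)^2)), 0.01)
})

test_that("membrane profile training recovers the generating profile from polarized images", {
  truth <- initial_profiles(50, centre = 26.5, width = 3)
  gen <- gen_cortex_images(n_cyt = 4, n_pol = 5, L = 60, profiles = truth,
                           noise_sd = 0, seed = 13)
  cyt_fit <- train_cyt_profile(gen$cyt_images)
  fit <- train_mem_profile(gen$pol_images, cyt_fit$s_cyt)
  expect_lt(sqrt(mean((fit$s_mem - truth$s_mem)^2)), 1e-3)
  expect_equal(max(fit$s_mem), 1, tolerance = 1e-12)
  expect_equal(fit$c_cyt, gen$truth$c_cyt_pol, tolerance = 1e-3)

  # stability: a disjoint batch from the same generator agrees within noise
  gen2 <- gen_cortex_images(n_cyt = 2, n_pol = 5, L = 60, profiles = truth,
                            noise_sd = 0.02, seed = 14)
  fit2 <- train_mem_profile(gen2$pol_images, cyt_fit$s_cyt)
  expect_lt(sqrt(mean((fit2$s_mem - fit$s_mem)^2)), 0.03)

  # uniform membranes are rejected as unidentifiable
  genU <- gen_cortex_images(n_cyt = 2, n_pol = 3, L = 60, profiles = truth,
                            mem_contrast = 1, noise_sd = 0, seed = 15)
  expect_error(train_mem_profile(genU$pol_images, cyt_fit$s_cyt),
               "contrast")
})

test_that("unit calibration from an optogenetic redistribution pair", {
  # direct arithmetic: (100 - 80) / (0.174 um^-1 * (150 - 50)) = 1.149 um
  f <- calibrate_units(100, 80, 50, 150, 0.174e6)
  expect_equal(f * 1e6, 1.149, tolerance = 1e-3)
  expect_error(calibrate_units(100, 100, 50, 50, 0.174e6), "M' = M")

  gen <- gen_optogenetic_pair(true_factor = 1.2e-6, cv = 0, seed = 4)
  o <- gen$observed
  expect_equal(calibrate_units(o$C, o$C_after, o$M, o$M_after, o$psi),
               1.2e-6, tolerance = 1e-10)
  # conservation is built into the generator
  expect_equal(o$C + o$psi * 1.2e-6 * o$M,
               o$C_after + o$psi * 1.2e-6 * o$M_after, tolerance = 1e-9)
})

test_that("polarity metrics summarize membrane profiles correctly", {
  psi <- 0.174e6
  L <- 100
  # uniform membrane: posterior mean = global mean = peak
  resU <- list(c_cyt = 2, c_mem = rep(3, L))
  mU <- polarity_metrics(resU, factor = 1 / psi, psi = psi)
  expect_equal(mU$posterior_mem, 3)
  expect_equal(mU$peak_mem, 3, tolerance = 1e-12)
  expect_equal(mU$posterior_mc, 1.5)
  expect_equal(mU$fraction_pm, 3 / (2 + 3))

  # no membrane signal
  m0 <- polarity_metrics(list(c_cyt = 2, c_mem = rep(0, L)),
                         factor = 1 / psi, psi = psi)
  expect_equal(m0$fraction_pm, 0)
  expect_equal(m0$posterior_mc, 0)

  # posterior step x2 (posterior half 26:75 around the pole at 51):
  # posterior M:C doubles the anterior level
  c_mem <- rep(1, L)
  c_mem[26:75] <- 2
  resS <- list(c_cyt = 1, c_mem = c_mem)
  mS <- polarity_metrics(resS, factor = 1 / psi, psi = psi)
  expect_equal(mS$posterior_mem, 2)
  expect_equal(mS$peak_mem, 2, tolerance = 1e-12)

  # peak window is invariant to rotating the arc origin
  set.seed(6)
  c_rand <- runif(L)
  m1 <- polarity_metrics(list(c_cyt = 1, c_mem = c_rand),
                         factor = 1 / psi, psi = psi)
  m2 <- polarity_metrics(list(c_cyt = 1, c_mem = c_rand[c(31:L, 1:30)]),
                         factor = 1 / psi, psi = psi)
  expect_equal(m1$peak_mem, m2$peak_mem, tolerance = 1e-12)

  expect_error(polarity_metrics(resU, factor = 1 / psi, psi = psi,
                                posterior_frac = 2), "window")
})
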