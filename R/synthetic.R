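#' @title Synthetic-data generators
#' @description Seeded generators for every input the analysis consumes:
#'   graded-depletion rundown datasets, straightened-cortex image sets,
#'   SEC-MALS Mw curves, optogenetic calibration pairs and FRAP traces.
#'   Every generator returns the noisy observations together with the
#'   noiseless ground truth and the configuration (including the seed), and
#'   regenerating with the same seed is bit-identical. Noise touches only
#'   the observations, never the stored truth.
#' @name synthetic
NULL

#' Generate a graded-depletion (rundown) dataset from the equilibrium model
#'
#' Emulates an RNAi rundown: per-embryo totals are drawn log-uniformly over
#' `depletion_range` times `c_tot_baseline`, the two-compartment equilibrium
#' is solved for each, and independent multiplicative lognormal noise
#' (coefficient of variation `cv`) is applied to the membrane and cytoplasm
#' channels before scaling into arbitrary units.
#'
#' @param n_embryos Number of embryos.
#' @param kd_dim,kd_mem Dissociation constants of the generating model.
#' @param c_tot_baseline Undepleted total protein, molar (default 60 nM,
#'   which puts the wild-type cytoplasmic concentration near 11 nM at the
#'   default geometry).
#' @param depletion_range Fractions of baseline spanned (default 0.01-1,
#'   two decades, emulating a strong graded RNAi series).
#' @param cv Lognormal coefficient of variation per channel (default 0.10).
#' @param au_scale Multiplicative factors `c(cyt, mem)` converting molar to
#'   arbitrary units (default both 1e9, i.e. values read in nM).
#' @param genotype,condition Labels for the records.
#' @param a,psi Geometry (defaults as in [model_params()]).
#' @param seed Required integer seed.
#' @return A list: `observed` (a [rundown_dataset()] in AU), `truth`
#'   (noiseless molar data frame with `c_tot`, `cyt`, `mem`), `config`.
#' @export
gen_rundown <- function(n_embryos = 50, kd_dim = 425e-9, kd_mem = 10^-2.43,
                        c_tot_baseline = 60e-9,
                        depletion_range = c(0.01, 1), cv = 0.10,
                        au_scale = c(cyt = 1e9, mem = 1e9),
                        genotype = "wt", condition = "polarized",
                        a = 5e-9, psi = 0.174e6, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(cv >= 0, cv < 1, n_embryos > 0)
  set.seed(seed)
  frac <- 10^stats::runif(n_embryos, log10(depletion_range[1]),
                          log10(depletion_range[2]))
  c_tot <- frac * c_tot_baseline
  states <- lapply(c_tot, function(ct) {
    solve_equilibrium(model_params(kd_dim, kd_mem, ct, a = a, psi = psi))
  })
  cyt <- vapply(states, `[[`, numeric(1), "c_c")
  mem <- vapply(states, `[[`, numeric(1), "c_m")
  sdlog <- sqrt(log(1 + cv^2))
  noise <- function(x) {
    if (cv == 0) x else x * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog)
  }
  observed <- rundown_dataset(
    cyt = noise(cyt) * au_scale[["cyt"]],
    mem = noise(mem) * au_scale[["mem"]],
    genotype = genotype, condition = condition, units = "au")
  list(
    observed = observed,
    truth = data.frame(embryo_id = seq_len(n_embryos), c_tot = c_tot,
                       cyt = cyt, mem = mem),
    config = list(seed = seed, kd_dim = kd_dim, kd_mem = kd_mem,
                  c_tot_baseline = c_tot_baseline,
                  depletion_range = depletion_range, cv = cv,
                  au_scale = au_scale, a = a, psi = psi)
  )
}

#' Generate straightened-cortex training and test images
#'
#' Produces a cytoplasm-only set (for stage-one profile training) and a
#' polarized set (membrane concentration following a smooth logistic step,
#' low anterior / high posterior, wrapping at the poles) from known signal
#' profiles, with additive Gaussian pixel noise.
#'
#' @param n_cyt,n_pol Numbers of cytoplasm-only and polarized images.
#' @param H,L Image geometry (cross-membrane x arc pixels).
#' @param profiles True [signal_profiles()] (default [initial_profiles()]).
#' @param c_cyt_range Per-image uniform cytoplasmic concentrations are drawn
#'   uniformly in this range (raw units).
#' @param mem_contrast Posterior:anterior membrane ratio (1 = uniform).
#' @param mem_level Posterior membrane concentration scale (raw units).
#' @param noise_sd Additive Gaussian pixel noise (default 1% of the
#'   cytoplasmic plateau scale).
#' @param seed Required integer seed.
#' @return A list: `cyt_images`, `pol_images` (lists of matrices), `truth`
#'   (per-image `c_cyt` values and `c_mem` profiles, plus the generating
#'   profiles), `config`.
#' @export
gen_cortex_images <- function(n_cyt = 6, n_pol = 6, H = 50, L = 80,
                              profiles = initial_profiles(H),
                              c_cyt_range = c(1, 3), mem_contrast = 5,
                              mem_level = 2, noise_sd = 0.02, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  c_cyt_cyt <- stats::runif(n_cyt, c_cyt_range[1], c_cyt_range[2])
  c_cyt_pol <- stats::runif(n_pol, c_cyt_range[1], c_cyt_range[2])
  arc <- seq_len(L)
  # smooth periodic step: high around the posterior pole at L/2
  bump <- function(width = L / 8) {
    d <- pmin(abs(arc - (L / 2 + 1)), L - abs(arc - (L / 2 + 1)))
    1 / (1 + exp((d - L / 4) / width))
  }
  shape <- bump()
  c_mem_pol <- lapply(seq_len(n_pol), function(i) {
    lev <- mem_level * stats::runif(1, 0.8, 1.2)
    lev * (shape + 1 / (mem_contrast - 1 + 1e-12)) /
      (1 + 1 / (mem_contrast - 1 + 1e-12))
  })
  if (mem_contrast == 1) {
    c_mem_pol <- lapply(seq_len(n_pol), function(i) rep(mem_level, L))
  }
  cyt_images <- lapply(seq_len(n_cyt), function(i) {
    simulate_cortex_image(c_cyt_cyt[i], rep(0, L), profiles, noise_sd)
  })
  pol_images <- lapply(seq_len(n_pol), function(i) {
    simulate_cortex_image(c_cyt_pol[i], c_mem_pol[[i]], profiles, noise_sd)
  })
  list(
    cyt_images = cyt_images, pol_images = pol_images,
    truth = list(c_cyt_cyt = c_cyt_cyt, c_cyt_pol = c_cyt_pol,
                 c_mem_pol = c_mem_pol, profiles = profiles),
    config = list(seed = seed, H = H, L = L, mem_contrast = mem_contrast,
                  mem_level = mem_level, noise_sd = noise_sd)
  )
}

#' Generate a SEC-MALS weight-average molecular weight curve
#'
#' @param kd_dim True dimer dissociation constant, molar.
#' @param concentrations Input concentrations in mg/ml.
#' @param cv Multiplicative lognormal noise CV on Mw (default 0.01).
#' @param W_m Monomer molecular weight, kDa.
#' @param seed Required integer seed.
#' @return A list: `observed` (data frame `conc_mg_ml`, `mw_kda`), `truth`
#'   (noiseless Mw), `config`.
#' @export
gen_mw_curve <- function(kd_dim, concentrations = c(0.5, 0.75, 1, 2, 4, 7, 10),
                         cv = 0.01, W_m = 9.23474, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  mw_true <- weight_avg_mw(mass_to_molar(concentrations, W_m), kd_dim, W_m)
  sdlog <- sqrt(log(1 + cv^2))
  mw_obs <- if (cv == 0) mw_true else {
    mw_true * stats::rlnorm(length(mw_true), -sdlog^2 / 2, sdlog)
  }
  list(
    observed = data.frame(conc_mg_ml = concentrations, mw_kda = mw_obs),
    truth = data.frame(conc_mg_ml = concentrations, mw_kda = mw_true),
    config = list(seed = seed, kd_dim = kd_dim, cv = cv, W_m = W_m)
  )
}

#' Generate an optogenetic membrane-recruitment calibration pair
#'
#' Builds before/after mean cytoplasmic and membrane signals consistent with
#' a conserved total `T = C + psi * factor * M`, then perturbs the four
#' readouts with multiplicative noise.
#'
#' @param true_factor True unit conversion factor (metres).
#' @param psi Surface-to-volume ratio, 1/m.
#' @param C_before Cytoplasmic signal before recruitment (raw units).
#' @param recruited_fraction Fraction of the cytoplasmic pool moved to the
#'   membrane (default 0.3).
#' @param M_before Membrane signal before recruitment (raw membrane units).
#' @param cv Multiplicative noise CV on each readout (default 0).
#' @param seed Required integer seed.
#' @return A list: `observed` (`C`, `C_after`, `M`, `M_after`, `psi`),
#'   `truth` (the noiseless record and `factor`), `config`.
#' @export
gen_optogenetic_pair <- function(true_factor, psi = 0.174e6, C_before = 100,
                                 recruited_fraction = 0.3, M_before = 20,
                                 cv = 0, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  moved <- recruited_fraction * C_before
  C_after <- C_before - moved
  M_after <- M_before + moved / (psi * true_factor)
  obs <- c(C = C_before, C_after = C_after, M = M_before, M_after = M_after)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    obs <- obs * stats::rlnorm(4, -sdlog^2 / 2, sdlog)
  }
  list(
    observed = c(as.list(obs), psi = psi),
    truth = list(C = C_before, C_after = C_after, M = M_before,
                 M_after = M_after, factor = true_factor),
    config = list(seed = seed, psi = psi, cv = cv,
                  recruited_fraction = recruited_fraction)
  )
}

#' Generate a FRAP trace pair (bleach + control ROI)
#'
#' Single-exponential recovery at rate `k` after a bleach to depth `depth`,
#' sampled at `dt` intervals, with shared multiplicative acquisition drift
#' applied to both ROIs (which [normalize_frap()] must cancel) plus
#' independent Gaussian measurement noise.
#'
#' @param k Recovery rate, 1/s.
#' @param depth Bleach depth as a fraction of the prebleach signal removed.
#' @param n_pre,n_post Numbers of prebleach and postbleach frames.
#' @param dt Frame interval, seconds (default 0.5).
#' @param drift Linear drift per frame applied to both ROIs (default 0).
#' @param noise_sd Additive Gaussian noise SD, in prebleach-signal units.
#' @param seed Required integer seed.
#' @return A list: `bleach`, `control`, `t` (seconds), `bleach_index`,
#'   `truth` (noiseless bleach series and `k`), `config`.
#' @export
gen_frap_trace <- function(k = 0.0073, depth = 0.8, n_pre = 15, n_post = 600,
                           dt = 0.5, drift = 0, noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  n <- n_pre + n_post
  bleach_index <- n_pre + 1L
  t <- (seq_len(n) - bleach_index) * dt
  base <- 1
  recovery <- ifelse(t < 0, base, base * (1 - depth * exp(-k * pmax(t, 0))))
  control <- rep(base, n)
  drift_mult <- 1 + drift * (seq_len(n) - 1)
  obs_b <- recovery * drift_mult
  obs_c <- control * drift_mult
  if (noise_sd > 0) {
    obs_b <- obs_b + stats::rnorm(n, sd = noise_sd)
    obs_c <- obs_c + stats::rnorm(n, sd = noise_sd)
  }
  list(
    bleach = obs_b, control = obs_c, t = t, bleach_index = bleach_index,
    truth = list(series = recovery, k = k, depth = depth),
    config = list(seed = seed, k = k, depth = depth, dt = dt,
                  drift = drift, noise_sd = noise_sd)
  )
}
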