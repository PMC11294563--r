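#!/usr/bin/env Rscript
# Straightened-cortex image quantification, end to end on synthetic data:
# train the cytoplasmic profile on cytoplasm-only images, the membrane
# profile on polarized images, quantify held-out images, calibrate units
# from a simulated optogenetic recruitment pair, and compute polarity
# metrics. Finishes with FRAP normalization and off-rate recovery.

library(par2coop)
dir.create("results", showWarnings = FALSE)

seed <- 11
truth <- initial_profiles(50, centre = 26.5, width = 3) # generating profiles
gen <- gen_cortex_images(n_cyt = 8, n_pol = 8, H = 50, L = 80,
                         profiles = truth, noise_sd = 0.02, seed = seed)

cyt_fit <- train_cyt_profile(gen$cyt_images)
mem_fit <- train_mem_profile(gen$pol_images, cyt_fit$s_cyt)
cat(sprintf("profile training: s_cyt RMS error %.2g (%d iters), s_mem %.2g (%d iters)\n",
            sqrt(mean((cyt_fit$s_cyt - truth$s_cyt)^2)), cyt_fit$iterations,
            sqrt(mean((mem_fit$s_mem - truth$s_mem)^2)), mem_fit$iterations))
jsonlite::write_json(
  list(s_cyt = cyt_fit$s_cyt, s_mem = mem_fit$s_mem,
       provenance = mem_fit$profiles$provenance),
  "results/trained_profiles.json", auto_unbox = TRUE, digits = NA)

# Quantify a held-out polarized image and compare to generator truth
held <- gen_cortex_images(n_cyt = 1, n_pol = 3, H = 50, L = 80,
                          profiles = truth, noise_sd = 0.02, seed = seed + 1)
q <- quantify_image(held$pol_images[[1]], mem_fit$profiles)
cat(sprintf("held-out image: c_cyt = %.3f (truth %.3f), mean c_mem error %.2g\n",
            q$c_cyt, held$truth$c_cyt_pol[1],
            mean(abs(q$c_mem - held$truth$c_mem_pol[[1]]))))

# Unit calibration from an optogenetic redistribution pair
psi <- 0.174e6
opto <- gen_optogenetic_pair(true_factor = 1.2e-6, psi = psi, cv = 0.01,
                             seed = seed + 2)
o <- opto$observed
factor <- calibrate_units(o$C, o$C_after, o$M, o$M_after, o$psi)
cat(sprintf("unit conversion factor: %.3f um (truth %.3f um)\n",
            factor * 1e6, 1.2))

metrics <- polarity_metrics(q, factor = factor, psi = psi)
cat(sprintf("posterior M:C = %.2f, fraction at PM = %.3f, peak window = %.3f\n",
            metrics$posterior_mc, metrics$fraction_pm, metrics$peak_mem))
utils::write.csv(
  data.frame(arc_px = seq_along(metrics$local_mc), local_mc = metrics$local_mc),
  "results/local_mc_profile.csv", row.names = FALSE)

# FRAP: normalize and recover the reference off-rate 0.0073 1/s
fr <- gen_frap_trace(k = 0.0073, depth = 0.8, noise_sd = 0.002,
                     seed = seed + 3)
norm <- normalize_frap(fr$bleach, fr$control, fr$bleach_index)
pi <- attr(norm, "post_index")
idx <- pi:length(norm)
rate <- fit_frap_rate(fr$t[idx], norm[idx])
cat(sprintf("FRAP off-rate: fitted %.5f 1/s (truth 0.00730)\n", rate$k))
jsonlite::write_json(
  list(posterior_mc = metrics$posterior_mc, fraction_pm = metrics$fraction_pm,
       unit_factor_um = factor * 1e6, frap_k = rate$k, seed = seed),
  "results/image_quant_metrics.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
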