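#' @title End-to-end orchestration and model-figure tables
#' @description `run_pipeline()` chains the synthetic generators through
#'   profile training, image quantification, cooperativity scoring and the
#'   joint equilibrium fit, writing tidy CSV/JSON artifacts plus a hashed
#'   manifest. `reproduce_model_figures()` emits the model-derived figure
#'   panels (cooperativity landscape, equilibrium compartment fractions,
#'   kinetic-trapping trajectories and snapshots) as numeric tables.
#' @name pipeline
NULL

#' Run the synthetic end-to-end pipeline
#'
#' Stages (in dependency order): `simulate` (rundown datasets and cortex
#' image sets), `train` (signal profiles), `quantify` (image decomposition),
#' `score` (cooperativity with bootstrap), `fit` (joint two-genotype
#' equilibrium fit). All randomness is derived from `seed`; a repeated run
#' with the same seed produces byte-identical artifacts.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param stages Character subset of
#'   `c("simulate", "train", "quantify", "score", "fit")` (default all).
#'   Later stages require the artifacts of earlier ones within the same
#'   call.
#' @param n_embryos Embryos per genotype for the rundown stage.
#' @param n_boot Bootstrap replicates for the scoring stage.
#' @param image_geometry `c(H, L)` for the image stages.
#' @return Invisibly, a list of stage results; artifacts and
#'   `manifest.json` (file name, md5, seed) are written under `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed,
                         stages = c("simulate", "train", "quantify",
                                    "score", "fit"),
                         n_embryos = 40, n_boot = 1000,
                         image_geometry = c(H = 50, L = 80)) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  files <- character(0)
  H <- image_geometry[[1]]; L <- image_geometry[[2]]

  save_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  save_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, path)
  }
  need <- function(stage, dep) {
    if (is.null(res[[dep]])) {
      stop("stage '", stage, "' requires artifacts from stage '", dep,
           "'; include it in `stages`")
    }
  }

  if ("simulate" %in% stages) {
    res$simulate <- list(
      rundown = list(
        wt = gen_rundown(n_embryos, kd_dim = 425e-9, genotype = "wt",
                         seed = seed + 1),
        L109R = gen_rundown(n_embryos, kd_dim = 2550e-9, genotype = "L109R",
                            seed = seed + 2)
      ),
      images = gen_cortex_images(H = H, L = L, seed = seed + 3)
    )
    save_csv(rbind(res$simulate$rundown$wt$observed,
                   res$simulate$rundown$L109R$observed), "rundown_observed.csv")
    save_csv(rbind(cbind(genotype = "wt", res$simulate$rundown$wt$truth),
                   cbind(genotype = "L109R", res$simulate$rundown$L109R$truth)),
             "rundown_truth.csv")
  }
  if ("train" %in% stages) {
    need("train", "simulate")
    img <- res$simulate$images
    cyt_fit <- train_cyt_profile(img$cyt_images, H = H)
    mem_fit <- train_mem_profile(img$pol_images, cyt_fit$s_cyt)
    res$train <- list(cyt = cyt_fit, mem = mem_fit,
                      profiles = mem_fit$profiles)
    save_json(list(s_cyt = res$train$profiles$s_cyt,
                   s_mem = res$train$profiles$s_mem,
                   provenance = res$train$profiles$provenance),
              "profiles.json")
  }
  if ("quantify" %in% stages) {
    need("quantify", "train")
    img <- res$simulate$images
    quants <- lapply(img$pol_images, quantify_image,
                     profiles = res$train$profiles)
    res$quantify <- quants
    save_csv(data.frame(
      image = seq_along(quants),
      c_cyt = vapply(quants, `[[`, numeric(1), "c_cyt"),
      c_mem_mean = vapply(quants, function(q) mean(q$c_mem), numeric(1)),
      loss = vapply(quants, `[[`, numeric(1), "loss")
    ), "quantification.csv")
  }
  if ("score" %in% stages) {
    need("score", "simulate")
    sc <- coop_bootstrap(res$simulate$rundown$wt$observed,
                         n_boot = n_boot, seed = seed + 4)
    res$score <- sc
    save_json(list(alpha = sc$alpha, beta = sc$beta,
                   ci_low = unname(sc$ci["lower"]),
                   ci_high = unname(sc$ci["upper"]),
                   n = sc$n, n_boot = sc$n_boot, seed = sc$seed),
              "cooperativity.json")
  }
  if ("fit" %in% stages) {
    need("fit", "simulate")
    datasets <- lapply(res$simulate$rundown, function(g) {
      d <- g$observed
      # synthetic AU scale is known (nM), so units conversion is exact
      d$cyt <- d$cyt / g$config$au_scale[["cyt"]]
      d$mem <- d$mem / g$config$au_scale[["mem"]]
      d$units <- "molar"
      d
    })
    fit <- fit_joint(datasets, fit_spec(c("wt", "L109R")))
    res$fit <- fit
    save_json(list(kd_dim = as.list(fit$kd_dim), kd_mem = fit$kd_mem,
                   fold_change = as.list(fit$fold_change), loss = fit$loss),
              "fit.json")
  }

  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(
    list(seed = seed, stages = stages, files = manifest),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(res)
}

#' Model-figure tables
#'
#' Recomputes the model-derived figure panels as numeric tables:
#' \describe{
#'   \item{`fig3b`}{cooperativity landscape alpha over a
#'     `kd_dim` x `kd_mem` grid (c_tot sweep 27 to 0.27 nM,
#'     psi = 0.174 um^-1, a = 5 nm).}
#'   \item{`fig5a`}{equilibrium three-compartment fractions and PM:IM ratio
#'     over a `kd_dim` x `kd_mem` grid with `kd_int = 5 kd_mem`,
#'     psi = phi = 0.087 um^-1, c_tot = 27 nM.}
#'   \item{`fig5c`}{kinetic redistribution trajectories after opening the
#'     plasma-membrane compartment (lambda_tilde = 4 M/s), for weak,
#'     intermediate and strong dimerization, with the 600 s snapshot.}
#' }
#'
#' @param preset One of `"fig3b"`, `"fig5a"`, `"fig5c"`.
#' @param out_dir Optional directory to write `<preset>.csv` into.
#' @param fast If TRUE (default), use coarser grids/horizons suitable for
#'   routine runs; FALSE uses denser grids.
#' @return A data frame (also written as CSV when `out_dir` is given).
#' @export
reproduce_model_figures <- function(preset, out_dir = NULL, fast = TRUE) {
  presets <- c("fig3b", "fig5a", "fig5c")
  if (!preset %in% presets) {
    stop("unknown preset '", preset, "'; available: ",
         paste(presets, collapse = ", "))
  }
  n <- if (fast) 7 else 15
  tab <- switch(preset,
    fig3b = {
      kd_dim_grid <- 10^seq(-9, -3, length.out = n)
      kd_mem_grid <- 10^seq(-4, -1, length.out = max(3, n %/% 2))
      alpha <- cooperativity_landscape(kd_dim_grid, kd_mem_grid)
      data.frame(
        kd_dim = rep(kd_dim_grid, times = length(kd_mem_grid)),
        kd_mem = rep(kd_mem_grid, each = length(kd_dim_grid)),
        alpha = as.vector(alpha)
      )
    },
    fig5a = {
      kd_dim_grid <- 10^seq(-9, -5, length.out = n)
      kd_mem_grid <- 10^seq(-3.5, -1.5, length.out = max(3, n %/% 2))
      grid <- expand.grid(kd_dim = kd_dim_grid, kd_mem = kd_mem_grid)
      fr <- lapply(seq_len(nrow(grid)), function(i) {
        p <- model_params(grid$kd_dim[i], grid$kd_mem[i], 27e-9,
                          psi = 0.087e6, kd_int = 5 * grid$kd_mem[i],
                          phi = 0.087e6)
        compartment_fractions(solve_equilibrium(p, 3), p)
      })
      cbind(grid, do.call(rbind, lapply(fr, function(f) {
        data.frame(f_cyt = f$f_cyt, f_pm = f$f_pm, f_im = f$f_im,
                   pm_im_ratio = f$pm_im_ratio)
      })))
    },
    fig5c = {
      kd_dims <- c(weak = 3.58e-5, intermediate = 3.58e-7, strong = 3.58e-9)
      kd_mem_post <- 10^-2.43
      rows <- lapply(names(kd_dims), function(nm) {
        pre <- model_params(kd_dims[[nm]], 1, 27e-9, psi = 0.087e6,
                            kd_int = 5 * kd_mem_post, phi = 0.087e6)
        post <- model_params(kd_dims[[nm]], kd_mem_post, 27e-9,
                             psi = 0.087e6, kd_int = 5 * kd_mem_post,
                             phi = 0.087e6)
        traj <- simulate_symmetry_breaking(pre, post, lambda_tilde = 4,
                                           t_end = if (fast) 1e6 else 1e7)
        cbind(regime = nm, kd_dim = kd_dims[[nm]], traj$ts,
              f_pm_equilibrium = traj$target_fractions$f_pm)
      })
      do.call(rbind, rows)
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, paste0(preset, ".csv")),
                     row.names = FALSE)
  }
  tab
}
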