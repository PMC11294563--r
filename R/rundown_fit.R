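#' @title Fitting the equilibrium model to rundown data
#' @description Converts raw-unit rundown datasets to molar, predicts
#'   membrane from cytoplasmic concentration under the equilibrium model,
#'   and jointly fits per-genotype dimer affinities with a shared membrane
#'   partition constant, with bootstrap confidence intervals.
#' @name rundown_fit
NULL

#' Normalize a rundown dataset to molar units
#'
#' Applies a single multiplicative factor to both channels so that the mean
#' cytoplasmic value of a designated reference subset (wild-type polarized
#' embryos by default) equals a known absolute concentration (10.4 nM for
#' PAR-2). The membrane channel is additionally divided by the slab thickness
#' `a` to express the per-area membrane signal as a slab concentration.
#'
#' @param data A [rundown_dataset()] in raw AU.
#' @param reference_c_c Absolute cytoplasmic concentration of the reference
#'   subset, molar (default 10.4e-9).
#' @param reference Logical vector, or NULL to use
#'   `genotype == "wt" & condition == "polarized"`.
#' @param a Slab thickness in metres; set `a = 1` if the membrane channel is
#'   already a slab concentration in the same per-volume units as `cyt`.
#' @return The dataset with `cyt`, `mem` in molar and `units = "molar"`.
#' @export
normalize_to_molar <- function(data, reference_c_c = 10.4e-9,
                               reference = NULL, a = 1) {
  stopifnot(is.data.frame(data), reference_c_c > 0, a > 0)
  if (is.null(reference)) {
    reference <- data$genotype == "wt" & data$condition == "polarized"
  }
  if (!any(reference)) stop("reference subset is empty")
  scale <- reference_c_c / mean(data$cyt[reference])
  data$cyt <- data$cyt * scale
  data$mem <- data$mem * scale / a
  data$units <- "molar"
  data
}

#' Equilibrium membrane concentration implied by a cytoplasmic concentration
#'
#' Inverts the chemical-potential equality
#' `activity(c_c) = kd_mem * activity(c_m)` in closed form. The log-log slope
#' of this map runs from 1 (monomer and double-dimer limits) through values
#' up to 2 in the transition region -- the source of apparent cooperativity.
#'
#' @param c_c Cytoplasmic concentration(s), molar.
#' @param kd_dim,kd_mem Dissociation constants.
#' @return Membrane slab concentration(s), molar.
#' @export
predict_membrane <- function(c_c, kd_dim, kd_mem) {
  stopifnot(all(c_c >= 0), kd_dim > 0, kd_mem > 0)
  activity_to_conc(reduced_activity(c_c, kd_dim) / kd_mem, kd_dim)
}

#' Specify a joint rundown fit
#'
#' @param genotypes Character vector of genotype labels to fit (order fixes
#'   the parameter layout; the first is the reference for fold-changes).
#' @param fixed_kd_dim Named numeric of genotypes whose `kd_dim` is fixed
#'   (e.g. `c(wt = 358e-9)` to constrain to the AUC value); others are free.
#' @param log10_kd_dim_bounds,log10_kd_mem_bounds Parameter bounds in log10
#'   space (defaults: kd_dim in [1 nM, 100 uM], kd_mem in [1e-5, 1]).
#' @param n_starts Number of multi-start simplex restarts (log-uniform grid
#'   over the bounds, deterministic).
#' @return A list of class `"fit_spec"`.
#' @export
fit_spec <- function(genotypes, fixed_kd_dim = numeric(0),
                     log10_kd_dim_bounds = c(-9, -4),
                     log10_kd_mem_bounds = c(-5, 0),
                     n_starts = 8) {
  stopifnot(length(genotypes) >= 1, n_starts >= 1,
            all(names(fixed_kd_dim) %in% genotypes))
  structure(list(genotypes = genotypes, fixed_kd_dim = fixed_kd_dim,
                 kd_dim_bounds = log10_kd_dim_bounds,
                 kd_mem_bounds = log10_kd_mem_bounds,
                 n_starts = n_starts),
            class = "fit_spec")
}

# Sum of squared residuals of log10 membrane concentration across genotypes.
.rundown_loss <- function(theta, datasets, spec) {
  free <- setdiff(spec$genotypes, names(spec$fixed_kd_dim))
  kd_dim <- c(10^theta[seq_along(free)], spec$fixed_kd_dim)
  names(kd_dim)[seq_along(free)] <- free
  kd_mem <- 10^theta[length(free) + 1]
  loss <- 0
  for (g in spec$genotypes) {
    d <- datasets[[g]]
    pred <- predict_membrane(d$cyt, kd_dim[[g]], kd_mem)
    loss <- loss + sum((log10(pred) - log10(d$mem))^2)
  }
  loss
}

#' Jointly fit per-genotype dimer affinities with a shared membrane constant
#'
#' Minimizes the summed squared residuals of `log10(membrane)` across
#' genotypes, with one free `kd_dim` per genotype (unless fixed in the spec)
#' and a single shared `kd_mem`. Optimization is multi-start Nelder-Mead in
#' log10 parameter space over a deterministic log-uniform start grid; the
#' best start wins, ties broken toward the lowest `kd_dim` of the first
#' genotype.
#'
#' @param datasets Named list of molar [rundown_dataset()]s, one per genotype
#'   in `spec$genotypes`.
#' @param spec A [fit_spec()].
#' @return A list of class `"fit_result"`: `kd_dim` (named per genotype),
#'   `kd_mem`, `loss`, `fold_change` (kd_dim relative to the first genotype),
#'   `at_bound` flag, and the per-start table `starts`.
#' @export
fit_joint <- function(datasets, spec) {
  stopifnot(inherits(spec, "fit_spec"),
            all(spec$genotypes %in% names(datasets)))
  for (g in spec$genotypes) {
    if (!all(datasets[[g]]$units == "molar")) {
      stop("dataset for genotype '", g, "' is not in molar units; ",
           "run normalize_to_molar() first")
    }
  }
  free <- setdiff(spec$genotypes, names(spec$fixed_kd_dim))
  npar <- length(free) + 1L
  lower <- c(rep(spec$kd_dim_bounds[1], length(free)), spec$kd_mem_bounds[1])
  upper <- c(rep(spec$kd_dim_bounds[2], length(free)), spec$kd_mem_bounds[2])

  # deterministic log-uniform multi-start grid (quasi-random via radical
  # inverse so starts fill the box without a seed)
  radical_inverse <- function(i, base) {
    f <- 1 / base; r <- 0
    while (i > 0) {
      r <- r + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    r
  }
  primes <- c(2, 3, 5, 7, 11, 13)
  starts <- t(vapply(seq_len(spec$n_starts), function(i) {
    u <- vapply(seq_len(npar), function(j) radical_inverse(i, primes[j]),
                numeric(1))
    lower + u * (upper - lower)
  }, numeric(npar)))

  runs <- lapply(seq_len(nrow(starts)), function(i) {
    o <- stats::optim(starts[i, ], .rundown_loss, datasets = datasets,
                      spec = spec, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    list(par = pmin(pmax(o$par, lower), upper), value = o$value,
         convergence = o$convergence)
  })
  losses <- vapply(runs, `[[`, numeric(1), "value")
  first_kd <- vapply(runs, function(r) r$par[1], numeric(1))
  best <- order(round(losses, 12), first_kd)[1]
  par <- runs[[best]]$par

  kd_dim <- c(stats::setNames(10^par[seq_along(free)], free),
              spec$fixed_kd_dim)[spec$genotypes]
  kd_mem <- 10^par[npar]
  at_bound <- any(abs(par - lower) < 1e-6) || any(abs(par - upper) < 1e-6)
  if (at_bound) warning("fit converged at a parameter bound")
  structure(
    list(kd_dim = kd_dim, kd_mem = kd_mem,
         loss = runs[[best]]$value,
         fold_change = kd_dim / kd_dim[[1]],
         at_bound = at_bound,
         starts = data.frame(loss = losses, converged = vapply(
           runs, function(r) r$convergence == 0, logical(1)))),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Joint equilibrium-model fit\n")
  for (g in names(x$kd_dim)) {
    cat(sprintf("  kd_dim[%s] = %.4g M (%.2f-fold vs %s)",
                g, x$kd_dim[[g]], x$fold_change[[g]], names(x$kd_dim)[1]))
    if (!is.null(x$ci_kd_dim) && g %in% rownames(x$ci_kd_dim)) {
      cat(sprintf("  95%% CI [%.3g, %.3g]",
                  x$ci_kd_dim[g, 1], x$ci_kd_dim[g, 2]))
    }
    cat("\n")
  }
  cat(sprintf("  shared kd_mem = %.4g (loss %.4g)\n", x$kd_mem, x$loss))
  invisible(x)
}

#' Bootstrap confidence intervals for the joint fit
#'
#' Resamples embryos with replacement within each genotype and refits;
#' fold-changes are computed within each replicate so their CI respects the
#' correlation between the genotype estimates.
#'
#' @inheritParams fit_joint
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed (required).
#' @return The point-estimate `"fit_result"` augmented with `boot` (matrix of
#'   replicate parameters), `ci_kd_dim`, `ci_kd_mem`, `ci_fold_change`.
#' @export
bootstrap_fit <- function(datasets, spec, n_boot = 200, seed) {
  if (missing(seed)) stop("seed is required")
  point <- fit_joint(datasets, spec)
  G <- spec$genotypes
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(G) + 1,
                 dimnames = list(NULL, c(G, "kd_mem")))
  for (b in seq_len(n_boot)) {
    res <- lapply(datasets[G], function(d) {
      d[sample.int(nrow(d), nrow(d), replace = TRUE), , drop = FALSE]
    })
    fit <- suppressWarnings(fit_joint(res, spec))
    boot[b, ] <- c(fit$kd_dim, fit$kd_mem)
  }
  ci <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  point$boot <- boot
  point$ci_kd_dim <- t(apply(boot[, G, drop = FALSE], 2, ci))
  colnames(point$ci_kd_dim) <- c("lower", "upper")
  point$ci_kd_mem <- ci(boot[, "kd_mem"])
  fold <- boot[, G, drop = FALSE] / boot[, G[1]]
  point$ci_fold_change <- t(apply(fold, 2, ci))
  colnames(point$ci_fold_change) <- c("lower", "upper")
  point$seed <- seed
  point$n_boot <- n_boot
  point
}
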