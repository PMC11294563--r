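#' @title Equilibrium model of dimerization coupled to membrane binding
#' @description Core thermodynamic machinery: mass-action monomer/dimer
#'   partition, the reduced activity (exponential of the chemical potential up
#'   to compartment-independent constants), the equilibrium solver for two- or
#'   three-compartment systems, compartment occupancy fractions, and the
#'   cooperativity landscape over dissociation-constant grids.
#' @name thermo
NULL

#' Crowding factor D(c) of the dimerization chemical potential
#'
#' `D(c) = 1 + 4 c / K + sqrt(1 + 8 c / K)`. Appears under a square root in
#' both the chemical potentials and the kinetic rate expressions. `D(0) = 2`.
#'
#' @param c Total (monomer-equivalent) concentration, molar. Vectorized.
#' @param kd_dim Dimer dissociation constant, molar.
#' @return Numeric vector, `>= 2`.
#' @export
dimer_D <- function(c, kd_dim) {
  stopifnot(all(c >= 0), kd_dim > 0)
  1 + 4 * c / kd_dim + sqrt(1 + 8 * c / kd_dim)
}

#' Monomer/dimer partition at dimerization equilibrium
#'
#' Splits a total concentration `c` into monomer `c1` and dimer `c2`
#' (monomer-equivalent units) satisfying mass action
#' `c1^2 / (c2 / 2) = kd_dim` and conservation `c1 + c2 = c`:
#' `c1 = (K/4) (sqrt(1 + 8 c / K) - 1)`, `c2 = c - c1`.
#'
#' @inheritParams dimer_D
#' @return A list with numeric vectors `c1` and `c2`.
#' @examples
#' dimer_partition(358e-9, 358e-9) # c = K: exactly half monomer, half dimer
#' @export
dimer_partition <- function(c, kd_dim) {
  stopifnot(is.numeric(c), is.numeric(kd_dim), kd_dim > 0)
  if (any(c < 0)) stop("concentrations must be nonnegative")
  s <- sqrt(1 + 8 * c / kd_dim)
  # (K/4)(s - 1) rewritten as 2c/(1 + s): avoids the s - 1 cancellation
  # (and its mass-action error) in the dilute regime c << K
  c1 <- 2 * c / (1 + s)
  # c - c1 rewritten via s - 1 = (8 c / K)/(1 + s): no cancellation, and
  # mass action c1^2/(c2/2) = K holds to machine precision in all regimes
  c2 <- 8 * c^2 / (kd_dim * (1 + s)^2)
  list(c1 = c1, c2 = c2)
}

#' Reduced activity of a dimerizing species
#'
#' The exponential of the chemical potential, stripped of the additive
#' constants shared by all compartments and normalized so that the dilute
#' (all-monomer) limit returns `c` itself:
#' `activity(c) = c * sqrt(2 / D(c))`. This is algebraically identical to the
#' equilibrium monomer concentration `c1(c)`, which makes the activity
#' trivially invertible: `c = c1 + 2 c1^2 / kd_dim`. Equality of
#' `kd * activity` across compartments defines chemical equilibrium; the
#' normalization constant cancels there.
#'
#' @inheritParams dimer_D
#' @return Numeric vector; strictly increasing in `c`.
#' @export
reduced_activity <- function(c, kd_dim) {
  if (any(c < 0)) stop("concentrations must be nonnegative")
  dimer_partition(c, kd_dim)$c1
}

#' Invert the reduced activity
#'
#' Total concentration whose reduced activity (= monomer concentration)
#' equals `act`: `c = act + 2 act^2 / kd_dim`.
#'
#' @param act Reduced activity (molar). Vectorized.
#' @param kd_dim Dimer dissociation constant, molar.
#' @return Total concentration, molar.
#' @export
activity_to_conc <- function(act, kd_dim) {
  stopifnot(all(act >= 0), kd_dim > 0)
  act + 2 * act^2 / kd_dim
}

# Membrane concentrations implied by a cytoplasmic concentration via the
# equilibrium condition activity(c_c) = kd * activity(c_m).
.implied_membrane <- function(c_c, kd, kd_dim) {
  activity_to_conc(reduced_activity(c_c, kd_dim) / kd, kd_dim)
}

#' Solve the coupled dimerization/membrane-binding equilibrium
#'
#' Finds the unique state satisfying (i) equality of chemical potentials
#' across compartments, `activity(c_c) = kd_mem * activity(c_m)`
#' (`= kd_int * activity(c_n)` for three compartments), and (ii) protein
#' conservation `c_tot = c_c + a (psi c_m + phi c_n)`. The activity equality
#' is inverted in closed form; conservation is solved by bracketed root
#' finding on `log10(c_c)` (bracket `[log10(c_tot) - 12, log10(c_tot)]`,
#' relative tolerance 1e-10), which is guaranteed to converge because the
#' total bound amount is strictly increasing in `c_c`.
#'
#' @param params A [model_params()] object.
#' @param n_compartments 2 (cytoplasm + plasma membrane) or 3 (+ internal
#'   membranes; requires `kd_int` and `phi`).
#' @return An object of class `"equilibrium_state"`: a list with compartment
#'   totals `c_c`, `c_m`, `c_n` (molar, slab units for membranes) and the
#'   per-compartment monomer/dimer breakdown `c1`, `c2` (named vectors).
#' @examples
#' p <- model_params(kd_dim = 425e-9, kd_mem = 10^-2.43, c_tot = 27e-9)
#' solve_equilibrium(p)
#' @export
solve_equilibrium <- function(params, n_compartments = 2) {
  stopifnot(inherits(params, "model_params"), n_compartments %in% c(2, 3))
  three <- n_compartments == 3
  if (three && (is.na(params$kd_int) || is.na(params$phi))) {
    stop("three-compartment model requires kd_int and phi")
  }
  kd_dim <- params$kd_dim
  if (params$c_tot == 0) {
    return(.equilibrium_state(0, 0, if (three) 0 else NA_real_, kd_dim))
  }

  totals <- function(c_c) {
    c_m <- .implied_membrane(c_c, params$kd_mem, kd_dim)
    c_n <- if (three) .implied_membrane(c_c, params$kd_int, kd_dim) else 0
    c_c + params$a * (params$psi * c_m + if (three) params$phi * c_n else 0)
  }
  resid <- function(lg) totals(10^lg) - params$c_tot

  lo <- log10(params$c_tot) - 12
  hi <- log10(params$c_tot)
  if (resid(lo) > 0 || resid(hi) < 0) {
    stop(sprintf(
      "equilibrium root not bracketed: residuals at log10(c_c) = [%g, %g] are [%g, %g]",
      lo, hi, resid(lo), resid(hi)
    ))
  }
  root <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
  c_c <- 10^root
  # polish on the linear scale (Newton-free: activity mapping is smooth)
  c_c <- tryCatch(
    stats::uniroot(function(x) totals(x) - params$c_tot,
                   c(c_c * (1 - 1e-4), c_c * (1 + 1e-4)),
                   tol = c_c * 1e-13, extendInt = "upX")$root,
    error = function(e) c_c
  )
  c_m <- .implied_membrane(c_c, params$kd_mem, kd_dim)
  c_n <- if (three) .implied_membrane(c_c, params$kd_int, kd_dim) else NA_real_
  .equilibrium_state(c_c, c_m, c_n, kd_dim)
}

.equilibrium_state <- function(c_c, c_m, c_n, kd_dim) {
  comps <- c(cytoplasm = c_c, membrane = c_m, internal = c_n)
  comps_ok <- comps[!is.na(comps)]
  part <- dimer_partition(comps_ok, kd_dim)
  structure(
    list(c_c = c_c, c_m = c_m, c_n = c_n,
         c1 = part$c1, c2 = part$c2, kd_dim = kd_dim),
    class = "equilibrium_state"
  )
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Equilibrium state (molar):\n")
  cat(sprintf("  cytoplasm: %.4g   membrane: %.4g", x$c_c, x$c_m))
  if (!is.na(x$c_n)) cat(sprintf("   internal: %.4g", x$c_n))
  cat("\n  monomer fractions:",
      paste(sprintf("%s %.3f", names(x$c1),
                    ifelse(x$c1 + x$c2 > 0, x$c1 / (x$c1 + x$c2), 1)),
            collapse = "  "), "\n")
  invisible(x)
}

#' Fraction of total protein in each compartment at equilibrium
#'
#' @param state A solved three-compartment [solve_equilibrium()] state.
#' @param params The [model_params()] used to solve it.
#' @return A list: `f_cyt`, `f_pm`, `f_im` (fractions summing to 1) and
#'   `pm_im_ratio` = (psi c_m)/(phi c_n), the plasma:internal membrane
#'   amount ratio.
#' @export
compartment_fractions <- function(state, params) {
  stopifnot(inherits(state, "equilibrium_state"))
  if (is.na(state$c_n)) stop("compartment_fractions needs a 3-compartment state")
  amt_c <- state$c_c
  amt_m <- params$a * params$psi * state$c_m
  amt_n <- params$a * params$phi * state$c_n
  tot <- amt_c + amt_m + amt_n
  list(
    f_cyt = amt_c / tot, f_pm = amt_m / tot, f_im = amt_n / tot,
    pm_im_ratio = if (amt_n > 0) amt_m / amt_n else Inf
  )
}

#' Cooperativity of the equilibrium model over a total-protein sweep
#'
#' Solves the two-compartment equilibrium across a log-spaced sweep of total
#' protein and returns the slope of `log10(c_m)` on `log10(c_c)` -- the
#' cooperativity score alpha of the model itself (noiseless).
#'
#' @param kd_dim,kd_mem Dissociation constants (see [model_params()]).
#' @param c_tot_sweep Molar totals to sweep. Default: 20 log-spaced values
#'   from 27 nM down to 0.27 nM.
#' @param a,psi Geometry, as in [model_params()].
#' @return Scalar alpha.
#' @export
score_model <- function(kd_dim, kd_mem,
                        c_tot_sweep = 10^seq(log10(27e-9), log10(0.27e-9),
                                             length.out = 20),
                        a = 5e-9, psi = 0.174e6) {
  states <- lapply(c_tot_sweep, function(ct) {
    solve_equilibrium(model_params(kd_dim, kd_mem, ct, a = a, psi = psi))
  })
  c_c <- vapply(states, `[[`, numeric(1), "c_c")
  c_m <- vapply(states, `[[`, numeric(1), "c_m")
  unname(stats::coef(stats::lm(log10(c_m) ~ log10(c_c)))[2])
}

#' Cooperativity landscape over dissociation-constant grids
#'
#' Evaluates [score_model()] on the outer grid `kd_dim_grid` x `kd_mem_grid`.
#' Solver failures in a grid cell are recorded as `NA` with a warning rather
#' than aborting the sweep.
#'
#' @param kd_dim_grid,kd_mem_grid Positive numeric grids.
#' @inheritParams score_model
#' @return A matrix of alpha values, rows = `kd_dim_grid`
#'   (dimnames carry the grid values).
#' @export
cooperativity_landscape <- function(kd_dim_grid, kd_mem_grid,
                                    c_tot_sweep = 10^seq(log10(27e-9),
                                                         log10(0.27e-9),
                                                         length.out = 20),
                                    a = 5e-9, psi = 0.174e6) {
  stopifnot(all(kd_dim_grid > 0), all(kd_mem_grid > 0))
  out <- matrix(NA_real_, length(kd_dim_grid), length(kd_mem_grid),
                dimnames = list(signif(kd_dim_grid, 6), signif(kd_mem_grid, 6)))
  for (i in seq_along(kd_dim_grid)) {
    for (j in seq_along(kd_mem_grid)) {
      out[i, j] <- tryCatch(
        score_model(kd_dim_grid[i], kd_mem_grid[j], c_tot_sweep,
                    a = a, psi = psi),
        error = function(e) {
          warning(sprintf("landscape cell (kd_dim=%g, kd_mem=%g) failed: %s",
                          kd_dim_grid[i], kd_mem_grid[j], conditionMessage(e)))
          NA_real_
        }
      )
    }
  }
  out
}
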