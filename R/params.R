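#' Model parameters for the dimerization / membrane-binding model
#'
#' Bundles the thermodynamic and geometric constants of the coupled
#' dimerization--membrane-partitioning model. Concentrations are molar
#' throughout; lengths are metres. The membrane is treated as a thin slab of
#' thickness `a` (the protein diameter) so that `a * psi` -- the dimensionless
#' slab-volume to cytoplasm-volume ratio -- converts slab concentrations into
#' cytoplasm-equivalent concentrations. The reference constants of the
#' underlying chemical potentials (gas constant, temperature, the 1 M
#' reference concentration and reference entropy) are common to all
#' compartments and cancel in every equilibrium condition, so they are not
#' parameters.
#'
#' @param kd_dim Molar dissociation constant for dimerization.
#' @param kd_mem Dimensionless plasma-membrane partition constant
#'   (larger = weaker binding).
#' @param c_tot Total protein concentration, molar (cytoplasm-volume units).
#' @param a Membrane slab thickness in metres (default 5 nm, the protein
#'   diameter).
#' @param psi Plasma-membrane surface-area to cytoplasm-volume ratio, 1/m
#'   (default 0.174 um^-1).
#' @param kd_int Dimensionless internal-membrane partition constant; required
#'   for the three-compartment model. `NA` disables the internal compartment.
#' @param phi Internal-membrane surface-area to cytoplasm-volume ratio, 1/m.
#'
#' @return An object of class `"model_params"` (a named list).
#' @examples
#' p <- model_params(kd_dim = 425e-9, kd_mem = 10^-2.43, c_tot = 27e-9)
#' @export
model_params <- function(kd_dim, kd_mem, c_tot,
                         a = 5e-9, psi = 0.174e6,
                         kd_int = NA_real_, phi = NA_real_) {
  stopifnot(
    is.numeric(kd_dim), length(kd_dim) == 1L, kd_dim > 0,
    is.numeric(kd_mem), length(kd_mem) == 1L, kd_mem > 0,
    is.numeric(c_tot), length(c_tot) == 1L, c_tot >= 0,
    a > 0, psi > 0
  )
  if (!is.na(kd_int)) {
    stopifnot(kd_int > 0, !is.na(phi), phi > 0)
  }
  structure(
    list(kd_dim = kd_dim, kd_mem = kd_mem, c_tot = c_tot,
         a = a, psi = psi, kd_int = kd_int, phi = phi),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Dimerization/membrane-binding model parameters\n")
  cat(sprintf("  kd_dim: %.4g M   kd_mem: %.4g   c_tot: %.4g M\n",
              x$kd_dim, x$kd_mem, x$c_tot))
  cat(sprintf("  a: %.3g nm   psi: %.3g um^-1", x$a * 1e9, x$psi * 1e-6))
  if (!is.na(x$kd_int)) {
    cat(sprintf("   kd_int: %.4g   phi: %.3g um^-1", x$kd_int, x$phi * 1e-6))
  }
  cat("\n")
  invisible(x)
}
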