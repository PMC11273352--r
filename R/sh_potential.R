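#' Second-harmonic intensity calibration
#'
#' Forward model for the SH response of a charged membrane interface:
#' the coherent SH amplitude is the sum of a chemical (second-order,
#' `chi2_effective`) term and a field-induced (effective third-order,
#' `chi3_prime`) term proportional to the transmembrane potential, and the
#' detected intensity is the squared amplitude times `intensity_scale`:
#'
#' \deqn{I = s\,(\chi^{(2)}_{eff} + \chi^{(3)'}\,\Delta\Phi_0)^2}
#'
#' For a compositionally symmetric bilayer the chemical terms of the two
#' leaflets cancel, so `chi2_effective = 0` and the potential magnitude is
#' proportional to the square root of the intensity.
#'
#' @param chi3_prime field-induced susceptibility amplitude per volt, > 0
#' @param intensity_scale detected counts per squared amplitude, > 0
#' @param chi2_effective residual chemical amplitude (default 0, symmetric
#'   membrane)
#' @param reference_potential optional anchor potential (V) recorded with the
#'   calibration (e.g. from capacitance minimization)
#' @return object of class `sh_calibration`
#' @export
sh_calibration <- function(chi3_prime = 1, intensity_scale = 1,
                           chi2_effective = 0, reference_potential = NULL) {
  stopifnot(chi3_prime > 0, intensity_scale > 0, chi2_effective >= 0)
  structure(list(chi3_prime = chi3_prime, intensity_scale = intensity_scale,
                 chi2_effective = chi2_effective,
                 reference_potential = reference_potential),
            class = "sh_calibration")
}

#' Anchor a calibration to a reference intensity/potential pair
#'
#' Fixes `intensity_scale` so that the given background-subtracted intensity
#' maps to the given potential (with `chi2_effective = 0`). Typical anchors:
#' the potential at which the capacitance-minimization protocol nulls the
#' membrane, or the brightest observed domain assigned to the top of the
#' observed potential range.
#'
#' @param intensity reference intensity, counts (> 0)
#' @param potential_V reference potential magnitude, V (> 0)
#' @param chi3_prime susceptibility amplitude per volt
#' @return an [sh_calibration()]
#' @export
#' @examples
#' cal <- calibrate_to_reference(2450, 0.35)
#' potential_from_intensity(2450, cal)  # 0.35
calibrate_to_reference <- function(intensity, potential_V, chi3_prime = 1) {
  stopifnot(intensity > 0, potential_V > 0)
  sh_calibration(chi3_prime = chi3_prime,
                 intensity_scale = intensity / (chi3_prime * potential_V)^2,
                 reference_potential = potential_V)
}

#' Transmembrane potential magnitude from SH intensity
#'
#' Inverts the forward model of [sh_calibration()] for the non-negative
#' potential magnitude. Intensity alone does not carry the sign of the
#' potential, so magnitudes are reported. With a nonzero chemical term the
#' inversion clamps at zero when the measured amplitude falls below it.
#'
#' @param intensity counts, >= 0 (vector/matrix/array accepted;
#'   background-subtract first)
#' @param cal an [sh_calibration()]
#' @return potential magnitude(s) in volts, same shape as `intensity`
#' @export
potential_from_intensity <- function(intensity, cal) {
  stopifnot(inherits(cal, "sh_calibration"))
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("negative intensity: subtract background and clamp before conversion")
  }
  amp <- sqrt(intensity / cal$intensity_scale)
  pmax(0, (amp - cal$chi2_effective)) / cal$chi3_prime
}

#' SH intensity from transmembrane potential (forward model)
#'
#' @param potential_V potential magnitude(s), V, >= 0
#' @param cal an [sh_calibration()]
#' @return intensity in counts
#' @export
intensity_from_potential <- function(potential_V, cal) {
  stopifnot(inherits(cal, "sh_calibration"), all(potential_V >= 0))
  cal$intensity_scale *
    (cal$chi2_effective + cal$chi3_prime * potential_V)^2
}

#' Parallel-plate capacitor model of the bilayer hydrophobic core
#'
#' @param eps dielectric constant of the hydrophobic core (default 2.1)
#' @param d_m core thickness in meters (default 4 nm)
#' @return object of class `capacitor_model` with derived areal capacitance
#'   `C` = eps0 * eps / d in F/m^2
#' @export
#' @examples
#' capacitor_model()$C  # ~4.6e-3 F/m^2 (0.46 uF/cm^2)
capacitor_model <- function(eps = 2.1, d_m = 4e-9) {
  stopifnot(eps > 1, d_m > 0)
  structure(list(eps = eps, d_m = d_m,
                 C = phys_constants$eps0 * eps / d_m),
            class = "capacitor_model")
}

#' Areal capacitance of a dielectric slab
#'
#' @inheritParams capacitor_model
#' @return eps0 * eps / d in F/m^2
#' @export
capacitance <- function(eps, d_m) {
  stopifnot(eps >= 1, d_m > 0)
  phys_constants$eps0 * eps / d_m
}

#' Surface charge density difference from a domain potential
#'
#' Capacitor relation `delta_sigma = C * delta_phi` per domain.
#'
#' @param delta_phi_V domain potential difference, V (vectorized)
#' @param cap a [capacitor_model()]
#' @return charge density difference in C/m^2
#' @export
charge_density_from_potential <- function(delta_phi_V, cap = capacitor_model()) {
  stopifnot(inherits(cap, "capacitor_model"))
  cap$C * delta_phi_V
}

#' Protons bound to a leaflet from a charge-density change
#'
#' Converts a per-domain surface-charge-density change and domain area into
#' a count of neutralizing protons, `N = delta_sigma * area / e`, and the
#' corresponding amount in moles. Counts are kept unrounded; round only when
#' reporting.
#'
#' @param delta_sigma charge density change, C/m^2 (vectorized)
#' @param area_m2 domain area, m^2 (> 0, recycled against `delta_sigma`)
#' @return object of class `charge_accounting` with fields `delta_sigma`,
#'   `area_m2`, `N` (count), `moles`
#' @export
bound_protons <- function(delta_sigma, area_m2) {
  if (any(!is.finite(area_m2)) || any(area_m2 <= 0)) {
    stop("domain area must be > 0")
  }
  N <- delta_sigma * area_m2 / phys_constants$e
  structure(list(delta_sigma = delta_sigma, area_m2 = area_m2,
                 N = N, moles = N / phys_constants$N_A),
            class = "charge_accounting")
}

#' @export
print.charge_accounting <- function(x, ...) {
  cat(sprintf(
    "Charge accounting over %d domain(s): N = %.4g protons (%.4g mol)\n",
    length(x$N), sum(x$N), sum(x$moles)))
  invisible(x)
}

#' Fraction of translocated protons retained at the interface
#'
#' Ratio of the electrically measured translocated amount to the
#' SH-imaging-derived interface-bound amount; conventionally reported as
#' "1 out of X" with X given to 2 significant figures.
#'
#' @param moles_translocated moles crossing the membrane (from current)
#' @param moles_bound moles neutralized at the receiving leaflet (from
#'   capacitor accounting)
#' @return list with `X` (exact ratio), `X_2sf` (2 significant figures) and
#'   `text` ("1 out of X")
#' @export
#' @examples
#' interface_retention_fraction(5.7e-14, 1.1e-17)$text  # "1 out of 5200"
interface_retention_fraction <- function(moles_translocated, moles_bound) {
  stopifnot(moles_translocated > 0, moles_bound > 0)
  X <- moles_translocated / moles_bound
  list(X = X, X_2sf = signif(X, 2),
       text = sprintf("1 out of %g", signif(X, 2)))
}
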