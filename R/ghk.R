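#' Goldman-Hodgkin-Katz single-ion current
#'
#' Constant-field (GHK) current carried by one ionic species across the
#' bilayer under an external bias U:
#'
#' \deqn{i = P z^2 \frac{F^2 U}{RT} A\,
#'       \frac{C_{in} - C_{out}\,e^{-zFU/RT}}{1 - e^{-zFU/RT}}}
#'
#' The "inside" compartment is the top (reference, pH 7.3) side and the
#' "outside" is the bottom compartment, matching the amplifier convention of
#' the acid-on-bottom experiment. At `U = 0` the expression reduces smoothly
#' to the diffusion-limited current `i = P z F A (C_in - C_out)`; at
#' symmetric concentrations the small-U slope is the Ohmic conductance
#' `G = P z^2 F^2 C A / (RT)`.
#'
#' @param P permeability, cm/s
#' @param U external voltage, V (may be a vector)
#' @param cond an [ion_conditions()] object; for protons (`species = "H"`)
#'   the compartment concentrations are taken from the pH fields
#' @param area_cm2 membrane area in cm^2
#' @param z ion valence (default +1, protons)
#' @param species which conducted species' concentrations to use,
#'   `"H"` or `"Cl"`
#' @return current in amperes
#' @export
#' @examples
#' cond <- ion_conditions()
#' ghk_current(3.7e-6, -0.06, cond, area_cm2 = 9503e-8)  # ~ -7 pA
ghk_current <- function(P, U, cond = ion_conditions(),
                        area_cm2, z = 1L, species = c("H", "Cl")) {
  species <- match.arg(species)
  stopifnot(inherits(cond, "ion_conditions"),
            is.numeric(P), P >= 0, is.numeric(U),
            is.numeric(area_cm2), area_cm2 > 0,
            z == round(z), z != 0)
  # concentrations in mol/cm^3 so that P [cm/s] * C [mol/cm^3] * A [cm^2]
  # * F [C/mol] is amperes
  if (species == "H") {
    c_in  <- cond$h_top / 1000
    c_out <- cond$h_bottom / 1000
  } else {
    c_in  <- cond$cl_top / 1000
    c_out <- cond$cl_bottom / 1000
  }
  vt <- thermal_voltage(cond$temperature)
  u <- z * U / vt                     # reduced voltage
  pref <- P * z * phys_constants$F * area_cm2
  small <- abs(u) < 1e-8
  out <- numeric(length(u))
  if (any(small)) {
    # series expansion around u = 0 (second order)
    us <- u[small]
    out[small] <- pref * ((c_in - c_out) +
      us * (c_in + c_out) / 2 + us^2 * (c_in - c_out) / 12)
  }
  if (any(!small)) {
    ub <- u[!small]
    out[!small] <- pref * ub * (c_in - c_out * exp(-ub)) / (1 - exp(-ub))
  }
  out
}

#' Small-signal (Ohmic) GHK conductance at symmetric concentrations
#'
#' @param P permeability, cm/s
#' @param conc concentration (both sides), mol/L
#' @param area_cm2 membrane area, cm^2
#' @param z ion valence
#' @param temperature kelvin
#' @return conductance in siemens
#' @export
ghk_ohmic_conductance <- function(P, conc, area_cm2, z = 1L,
                                  temperature = 296.15) {
  P * z^2 * phys_constants$F^2 * (conc / 1000) * area_cm2 /
    (phys_constants$R * temperature)
}

#' Permeability result container
#'
#' @param value permeability in cm/s
#' @param method one of `"ghk_current"`, `"sh_flux"`, `"eq4_profile"`
#' @param inputs_digest short text describing the inputs
#' @return object of class `permeability_result`
#' @export
permeability_result <- function(value, method, inputs_digest = "") {
  stopifnot(is.numeric(value), value > 0,
            method %in% c("ghk_current", "sh_flux", "eq4_profile"))
  structure(list(value = value, method = method,
                 inputs_digest = inputs_digest),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("Permeability: %.3e cm/s  [method: %s]\n", x$value, x$method))
  if (nzchar(x$inputs_digest)) cat("  inputs:", x$inputs_digest, "\n")
  invisible(x)
}

#' Permeability from a measured GHK current
#'
#' Exact algebraic inversion of [ghk_current()] for the permeability P; the
#' GHK current is linear in P, so `P = i / i(P = 1)`. Round-trips with
#' [ghk_current()] to machine precision.
#'
#' @param i measured current, A
#' @param U external voltage, V (nonzero)
#' @param cond an [ion_conditions()] object
#' @param area_cm2 membrane area, cm^2
#' @param z ion valence
#' @param species conducted species, `"H"` or `"Cl"`
#' @return a [permeability_result()] with method `"ghk_current"`
#' @export
#' @examples
#' permeability_from_current(-7.6e-12, -0.06, area_cm2 = 9503e-8)
permeability_from_current <- function(i, U, cond = ion_conditions(),
                                      area_cm2, z = 1L,
                                      species = c("H", "Cl")) {
  species <- match.arg(species)
  stopifnot(is.numeric(i), length(i) == 1L, i != 0,
            is.numeric(U), length(U) == 1L, U != 0)
  unit <- ghk_current(1, U, cond, area_cm2, z, species)
  P <- i / unit
  if (!is.finite(P) || P <= 0) {
    stop(paste0(
      "current and voltage signs are inconsistent with passive flow of ",
      species, " under these conditions (inside = top compartment; a ",
      "negative bias with acid on the bottom drives a negative proton ",
      "current)"))
  }
  permeability_result(P, "ghk_current",
                      sprintf("i=%.3g A, U=%.3g V, A=%.4g cm2, z=%d, %s",
                              i, U, area_cm2, z, species))
}

#' Permeability from an SH-derived ion flux
#'
#' Converts a translocation flux (ions/s) into a permeability via
#' `P = flux / (N_A * A * delta_c)` where `delta_c` is the driving
#' concentration difference.
#'
#' @param flux ion flux in ions/s
#' @param area_cm2 membrane area, cm^2
#' @param delta_c_mol_per_L concentration difference, mol/L (converted to
#'   mol/cm^3 internally); alternatively supply `cond` to use its
#'   transmembrane proton gradient
#' @param cond optional [ion_conditions()]; used when `delta_c_mol_per_L` is
#'   missing, taking `|[H]_bottom - [H]_top|`
#' @return a [permeability_result()] with method `"sh_flux"`
#' @export
#' @examples
#' permeability_from_flux(7.5e6, area_cm2 = 9503e-8)  # ~ 1.7e-6 cm/s
permeability_from_flux <- function(flux, area_cm2, delta_c_mol_per_L = NULL,
                                   cond = ion_conditions()) {
  stopifnot(is.numeric(flux), flux > 0, is.numeric(area_cm2), area_cm2 > 0)
  if (is.null(delta_c_mol_per_L)) {
    delta_c_mol_per_L <- abs(cond$h_bottom - cond$h_top)
  }
  if (!is.numeric(delta_c_mol_per_L) || delta_c_mol_per_L <= 0) {
    stop("zero concentration gradient: permeability undefined")
  }
  delta_c <- delta_c_mol_per_L / 1000  # mol/cm^3
  P <- flux / (phys_constants$N_A * area_cm2 * delta_c)
  permeability_result(P, "sh_flux",
                      sprintf("flux=%.3g ions/s, A=%.4g cm2, dC=%.3g mol/L",
                              flux, area_cm2, delta_c_mol_per_L))
}

#' Diffusion-limited permeability of an unstirred layer
#'
#' The static aqueous film adjacent to the membrane bounds the measurable
#' permeability at `P_UL = D / delta`.
#'
#' @param D diffusion coefficient of the proton carrier, cm^2/s
#' @param delta_cm unstirred layer thickness, cm
#' @return permeability bound in cm/s
#' @export
#' @examples
#' unstirred_layer_permeability(5e-6, 200e-4)  # 2.5e-4 cm/s
unstirred_layer_permeability <- function(D, delta_cm) {
  stopifnot(is.numeric(D), D >= 0, is.numeric(delta_cm), delta_cm > 0)
  D / delta_cm
}

#' Moles of ions transported by a zero-bias current
#'
#' For a constant current, `moles = |I| * t / F`. For a sampled time-varying
#' current supply `current` and `times` of equal length; the trace is
#' integrated trapezoidally.
#'
#' @param current current in A (scalar, or vector sampled at `times`)
#' @param duration_s duration in seconds (scalar current only)
#' @param times sample times in seconds (vector current only)
#' @return transported amount in moles
#' @export
#' @examples
#' transported_moles(2.54e-12, 3600)  # ~ 9.5e-14 mol
transported_moles <- function(current, duration_s = NULL, times = NULL) {
  if (length(current) == 1L) {
    stopifnot(is.numeric(duration_s), duration_s > 0)
    return(abs(current) * duration_s / phys_constants$F)
  }
  stopifnot(!is.null(times), length(times) == length(current),
            all(diff(times) > 0))
  y <- abs(current)
  integral <- sum(diff(times) * (head(y, -1) + tail(y, -1)) / 2)
  integral / phys_constants$F
}
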