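#' Proton concentration from pH
#'
#' Ideal-solution reading: activities are identified with concentrations,
#' so `[H+] = 10^(-pH)` mol/L exactly.
#'
#' @param pH dimensionless, in (0, 14)
#' @return proton concentration in mol/L
#' @export
#' @examples
#' proton_concentration(7)    # 1e-7
#' proton_concentration(4.1)  # 7.943e-5
proton_concentration <- function(pH) {
  if (!is.numeric(pH) || any(!is.finite(pH)) || any(pH <= 0) || any(pH >= 14)) {
    stop("pH must be finite and strictly between 0 and 14")
  }
  10^(-pH)
}

#' Ionic conditions of the two bilayer compartments
#'
#' Describes the aqueous solutions bathing the bottom and top leaflets of a
#' free-standing bilayer: pH, chloride and potassium concentrations, and
#' temperature. Proton concentrations are derived from pH assuming ideality.
#'
#' The packaged defaults describe the acid-gradient experiment: the bottom
#' compartment titrated to pH 4.1 with HCl (raising its ionic strength to
#' 61 mM), the top compartment at pH 7.3 in 50 mM KCl, at room temperature.
#'
#' @param pH_bottom,pH_top compartment pH values
#' @param cl_bottom,cl_top chloride concentrations, mol/L
#' @param k_bottom,k_top potassium concentrations, mol/L
#' @param temperature temperature, K
#' @return an object of class `ion_conditions`
#' @export
#' @examples
#' cond <- ion_conditions()            # acid-on-bottom defaults
#' cond$h_bottom / cond$h_top          # ~ 10^3.2 proton gradient
ion_conditions <- function(pH_bottom = 4.1, pH_top = 7.3,
                           cl_bottom = 0.061, cl_top = 0.050,
                           k_bottom = 0.050, k_top = 0.050,
                           temperature = 296.15) {
  conc <- c(cl_bottom = cl_bottom, cl_top = cl_top,
            k_bottom = k_bottom, k_top = k_top)
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("all ion concentrations must be finite and > 0")
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be finite and > 0 (kelvin)")
  }
  structure(list(
    pH_bottom = pH_bottom, pH_top = pH_top,
    h_bottom = proton_concentration(pH_bottom),
    h_top = proton_concentration(pH_top),
    cl_bottom = cl_bottom, cl_top = cl_top,
    k_bottom = k_bottom, k_top = k_top,
    temperature = temperature
  ), class = "ion_conditions")
}

#' @export
print.ion_conditions <- function(x, ...) {
  cat("Ion conditions (bottom / top):\n")
  cat(sprintf("  pH    : %.2f / %.2f  ([H+] %.3e / %.3e mol/L)\n",
              x$pH_bottom, x$pH_top, x$h_bottom, x$h_top))
  cat(sprintf("  [Cl-] : %.3f / %.3f mol/L\n", x$cl_bottom, x$cl_top))
  cat(sprintf("  [K+]  : %.3f / %.3f mol/L\n", x$k_bottom, x$k_top))
  cat(sprintf("  T     : %.2f K\n", x$temperature))
  invisible(x)
}

#' Circular membrane area from aperture radius
#'
#' @param radius_um aperture radius in micrometers
#' @return membrane area in square micrometers (pi * r^2)
#' @export
#' @examples
#' membrane_area(55)  # 9503 um^2
membrane_area <- function(radius_um) {
  stopifnot(is.numeric(radius_um), radius_um > 0)
  pi * radius_um^2
}
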