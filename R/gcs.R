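#' Gouy-Chapman-Stern parameters
#'
#' @param ionic_strength mol/L, > 0
#' @param eps_w relative permittivity of water (> 1)
#' @param stern_capacitance optional Stern (condensed) layer capacitance,
#'   F/m^2; `NULL` for a pure diffuse (Gouy-Chapman) double layer
#' @param temperature kelvin
#' @return object of class `gcs_params`
#' @export
gcs_params <- function(ionic_strength = 0.060, eps_w = 78.4,
                       stern_capacitance = NULL, temperature = 296.15) {
  stopifnot(ionic_strength > 0, eps_w > 1, temperature > 0)
  if (!is.null(stern_capacitance)) stopifnot(stern_capacitance > 0)
  structure(list(ionic_strength = ionic_strength, eps_w = eps_w,
                 stern_capacitance = stern_capacitance,
                 temperature = temperature),
            class = "gcs_params")
}

#' Surface potential from surface charge density (Gouy-Chapman-Stern)
#'
#' Solves the Grahame relation for a 1:1 electrolyte,
#' \deqn{\sigma = \sqrt{8\,\varepsilon_0\varepsilon_w R T c}\;
#'       \sinh\!\left(\frac{F\psi_d}{2RT}\right),}
#' for the diffuse-layer potential `psi_d` (closed form via asinh), and adds
#' the Stern-layer drop `sigma / C_stern` when a Stern capacitance is set.
#' The result is odd and strictly increasing in sigma. Without a Stern
#' layer the potential grows only logarithmically with sigma, which is why
#' potentials of several hundred mV at ~60 mM ionic strength require a
#' condensed (Stern) layer.
#'
#' @param sigma surface charge density, C/m^2 (vectorized)
#' @param p a [gcs_params()] object
#' @return surface potential in volts
#' @export
#' @examples
#' p <- gcs_params(0.060, stern_capacitance = 1)
#' gcs_surface_potential(0.05, p)
gcs_surface_potential <- function(sigma, p = gcs_params()) {
  stopifnot(inherits(p, "gcs_params"), is.numeric(sigma))
  RT <- phys_constants$R * p$temperature
  c_m3 <- p$ionic_strength * 1000            # mol/m^3
  a <- sqrt(8 * phys_constants$eps0 * p$eps_w * RT * c_m3)
  psi <- (2 * RT / phys_constants$F) * asinh(sigma / a)
  if (!is.null(p$stern_capacitance)) {
    psi <- psi + sigma / p$stern_capacitance
  }
  psi
}

#' Debye screening length
#'
#' @param p a [gcs_params()] object
#' @return Debye length 1/kappa in meters
#' @export
debye_length <- function(p = gcs_params()) {
  RT <- phys_constants$R * p$temperature
  c_m3 <- p$ionic_strength * 1000
  kappa <- sqrt(2 * phys_constants$F^2 * c_m3 /
                (phys_constants$eps0 * p$eps_w * RT))
  1 / kappa
}

#' Linearized (Debye-Hueckel) surface potential
#'
#' Small-charge limit `psi = sigma/(eps0 eps_w kappa) + sigma/C_stern`,
#' used as a closed-form check of [gcs_surface_potential()] for
#' |psi| below ~10 mV.
#'
#' @inheritParams gcs_surface_potential
#' @return potential in volts
#' @export
gcs_linearized_potential <- function(sigma, p = gcs_params()) {
  psi <- sigma * debye_length(p) / (phys_constants$eps0 * p$eps_w)
  if (!is.null(p$stern_capacitance)) psi <- psi + sigma / p$stern_capacitance
  psi
}

#' Surface charge density required for a target surface potential
#'
#' Numerical inverse of [gcs_surface_potential()] (monotone, bracketed by
#' uniroot). Useful for asking what lipid charge density a given
#' transmembrane potential implies with and without a Stern layer.
#'
#' @param psi target potential, V
#' @param p a [gcs_params()] object
#' @return sigma in C/m^2
#' @export
gcs_charge_for_potential <- function(psi, p = gcs_params()) {
  stopifnot(length(psi) == 1L, is.finite(psi))
  if (psi == 0) return(0)
  f <- function(s) gcs_surface_potential(s, p) - psi
  hi <- sign(psi) * 1e-6
  while (f(hi) * sign(psi) < 0 && abs(hi) < 1e6) hi <- hi * 10
  stats::uniroot(f, sort(c(0, hi)), tol = 1e-15)$root
}
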