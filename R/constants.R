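#' Physical constants (CODATA 2018)
#'
#' Constants used throughout the electrochemical formulas, in SI units.
#' Internal consistency (`R = k_B * N_A`, `F = e * N_A`) holds to better
#' than 1e-6 relative.
#'
#' @format A named list:
#' \describe{
#'   \item{R}{ideal gas constant, J mol^-1 K^-1}
#'   \item{F}{Faraday constant, C mol^-1}
#'   \item{e}{elementary charge, C}
#'   \item{eps0}{vacuum permittivity, F m^-1}
#'   \item{N_A}{Avogadro constant, mol^-1}
#'   \item{k_B}{Boltzmann constant, J K^-1}
#' }
#' @export
#' @examples
#' phys_constants$R / (phys_constants$k_B * phys_constants$N_A)  # 1
phys_constants <- list(
  R    = 8.31446261815324,
  F    = 96485.33212331001,
  e    = 1.602176634e-19,
  eps0 = 8.8541878128e-12,
  N_A  = 6.02214076e23,
  k_B  = 1.380649e-23
)

#' Thermal voltage RT/F
#'
#' @param temperature temperature in K
#' @return RT/F in volts
#' @export
thermal_voltage <- function(temperature = 296.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  phys_constants$R * temperature / phys_constants$F
}
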