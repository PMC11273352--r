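#' Goldman reversal potential for a H+/Cl- conducting membrane
#'
#' Constant-field (Goldman) reversal potential when the conducted species are
#' protons and chloride, parameterized by the permeability ratio
#' `r = P_H / P_Cl`:
#'
#' \deqn{V_m = \frac{RT}{F}\,\ln\frac{r\,[H]_{bottom} + [Cl]_{top}}
#'                                  {r\,[H]_{top} + [Cl]_{bottom}}}
#'
#' The sign convention makes `V_m > 0` when acid is added to the bottom
#' compartment and the membrane conducts protons better than chloride
#' (`r > 1`).
#'
#' @param r permeability ratio P_H/P_Cl, > 0 (may be `Inf` for the proton
#'   Nernst limit)
#' @param cond an [ion_conditions()] object
#' @return reversal potential in volts
#' @export
#' @examples
#' goldman_reversal(748, ion_conditions())   # ~ 0.015 V
#' goldman_reversal(Inf, ion_conditions())   # proton Nernst potential
goldman_reversal <- function(r, cond = ion_conditions()) {
  stopifnot(inherits(cond, "ion_conditions"))
  if (!is.numeric(r) || any(is.na(r)) || any(r <= 0)) {
    stop("permeability ratio r must be > 0")
  }
  vt <- thermal_voltage(cond$temperature)
  ifelse(is.infinite(r),
         vt * log(cond$h_bottom / cond$h_top),
         vt * log((r * cond$h_bottom + cond$cl_top) /
                  (r * cond$h_top + cond$cl_bottom)))
}

#' Attainable reversal-potential interval
#'
#' Limits of [goldman_reversal()] as r -> 0 (pure Cl- conduction, chloride
#' Nernst potential) and r -> Inf (pure H+ conduction, proton Nernst
#' potential). Any observable reversal potential lies strictly between them.
#'
#' @inheritParams goldman_reversal
#' @return numeric length-2 vector `c(lower, upper)` in volts
#' @export
reversal_limits <- function(cond = ion_conditions()) {
  vt <- thermal_voltage(cond$temperature)
  sort(c(vt * log(cond$cl_top / cond$cl_bottom),
         vt * log(cond$h_bottom / cond$h_top)))
}

#' Permeability ratio from a measured reversal potential
#'
#' Algebraic inversion of [goldman_reversal()] for `r = P_H/P_Cl`. The
#' Goldman expression is monotone in r whenever the two compartments differ,
#' so the solution is unique; `V_m` must lie strictly between the two
#' single-ion Nernst potentials (see [reversal_limits()]).
#'
#' @param V_m measured reversal potential, volts
#' @param cond an [ion_conditions()] object
#' @return permeability ratio P_H/P_Cl (dimensionless)
#' @export
#' @examples
#' permeability_ratio_from_reversal(0.015)  # > 50
permeability_ratio_from_reversal <- function(V_m, cond = ion_conditions()) {
  stopifnot(inherits(cond, "ion_conditions"), is.numeric(V_m), length(V_m) == 1L)
  if (cond$h_bottom == cond$h_top && cond$cl_bottom == cond$cl_top) {
    stop("symmetric conditions: any permeability ratio gives V_m = 0; ill-posed")
  }
  lim <- reversal_limits(cond)
  if (V_m <= lim[1] || V_m >= lim[2]) {
    stop(sprintf(
      "no solution: V_m = %.4g V outside the attainable interval (%.4g, %.4g) V",
      V_m, lim[1], lim[2]))
  }
  E <- exp(V_m / thermal_voltage(cond$temperature))
  r <- (E * cond$cl_bottom - cond$cl_top) / (cond$h_bottom - E * cond$h_top)
  if (!is.finite(r) || r <= 0) {
    stop("no positive permeability ratio is consistent with this V_m")
  }
  r
}
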