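#' Water-needle geometry
#'
#' @param radius_m needle radius, m (must be much smaller than the
#'   thickness; e.g. up to ~3 Angstrom)
#' @param thickness_m hydrophobic core thickness, m (default 4 nm)
#' @param eps_w water relative permittivity (default 80)
#' @param eps_m membrane core relative permittivity (default 2.1)
#' @return object of class `needle_geometry`
#' @export
needle_geometry <- function(radius_m = 3e-10, thickness_m = 4e-9,
                            eps_w = 80, eps_m = 2.1) {
  stopifnot(radius_m > 0, thickness_m > 0, radius_m < thickness_m,
            eps_w > eps_m, eps_m > 1)
  structure(list(radius_m = radius_m, thickness_m = thickness_m,
                 eps_w = eps_w, eps_m = eps_m),
            class = "needle_geometry")
}

#' Electrostatic stabilization energy of a water needle
#'
#' Dielectric-replacement capacitor model: a cylinder of water (eps_w)
#' spanning the hydrophobic core replaces membrane dielectric (eps_m) in the
#' uniform field U/d of the charged bilayer capacitor. The field energy
#' gained is
#' \deqn{\Delta W = \tfrac12\,\varepsilon_0(\varepsilon_w-\varepsilon_m)
#'       \left(\frac{U}{d}\right)^2 \pi r^2 d,}
#' reported per mole of needles (times Avogadro's number). Quadratic in both
#' the potential and the radius, and zero at U = 0.
#'
#' @param geom a [needle_geometry()]
#' @param U transmembrane potential, V (vectorized)
#' @return stabilization energy in kJ/mol
#' @export
#' @examples
#' needle_stabilization_energy(needle_geometry(3e-10), 0.3)  # ~1.3 kJ/mol
needle_stabilization_energy <- function(geom = needle_geometry(), U) {
  stopifnot(inherits(geom, "needle_geometry"), is.numeric(U))
  E <- U / geom$thickness_m
  dW_J <- 0.5 * phys_constants$eps0 * (geom$eps_w - geom$eps_m) * E^2 *
    pi * geom$radius_m^2 * geom$thickness_m
  dW_J * phys_constants$N_A / 1000
}

#' Defect free-energy and flux profiles along the chain coordinate
#'
#' Tabulated defect-formation free energy `dG(xi)` and proton flux `F(xi)`
#' on a common chain-coordinate grid. `xi = 0.1` is an unperturbed membrane
#' and `xi = 1` a completely open pore; `dG(xi_min) = 0` by offset
#' convention.
#'
#' @param xi chain-coordinate grid, strictly increasing within `[0.1, 1]`
#' @param dG_kJ_per_mol defect free energy, kJ/mol, with `dG[1] = 0`
#' @param flux proton flux, ions/s, all >= 0
#' @param voltage_V transmembrane potential the profiles were obtained at
#' @param label optional text (membrane composition)
#' @return object of class `defect_profiles`
#' @export
defect_profiles <- function(xi, dG_kJ_per_mol, flux, voltage_V = 0.3,
                            label = "") {
  stopifnot(length(xi) == length(dG_kJ_per_mol),
            length(xi) == length(flux),
            all(diff(xi) > 0), min(xi) >= 0.1 - 1e-9, max(xi) <= 1 + 1e-9,
            all(flux >= 0))
  if (abs(dG_kJ_per_mol[1]) > 1e-9) {
    stop("dG must be zero at the first grid point (offset convention)")
  }
  structure(list(xi = xi, dG = dG_kJ_per_mol, flux = flux,
                 voltage_V = voltage_V, label = label),
            class = "defect_profiles")
}

#' Read defect profiles from CSV
#'
#' Columns `xi, dG_kJ_per_mol, flux_ions_per_s`, one file per membrane and
#' voltage.
#'
#' @param path CSV path
#' @param voltage_V voltage annotation
#' @param label label (defaults to file name)
#' @return a [defect_profiles()]
#' @export
read_profiles_csv <- function(path, voltage_V = 0.3, label = basename(path)) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("xi", "dG_kJ_per_mol", "flux_ions_per_s")
  if (!all(need %in% names(df))) {
    stop(sprintf("file '%s' must have columns %s", path,
                 paste(need, collapse = ", ")))
  }
  o <- order(df$xi)
  defect_profiles(df$xi[o], df$dG_kJ_per_mol[o] - df$dG_kJ_per_mol[o][1],
                  df$flux_ions_per_s[o], voltage_V = voltage_V, label = label)
}

#' @param profiles a [defect_profiles()] to write
#' @rdname read_profiles_csv
#' @export
write_profiles_csv <- function(profiles, path) {
  stopifnot(inherits(profiles, "defect_profiles"))
  utils::write.csv(
    data.frame(xi = profiles$xi, dG_kJ_per_mol = profiles$dG,
               flux_ions_per_s = profiles$flux),
    path, row.names = FALSE)
  invisible(path)
}

#' Boltzmann-weighted permeability profile along the chain coordinate
#'
#' Combines the defect free-energy profile and the flux profile into a
#' relative permeability per chain coordinate,
#' \deqn{P(\xi) \propto F(\xi)\, e^{-\beta \Delta G_{defect}(\xi)},}
#' with `beta = 1/(RT)`. Also reported: the trapezoidal integral of P over
#' the grid and the dominant window, the smallest xi interval containing at
#' least 90 percent of the integral. Values are relative (an optional
#' prefactor rescales them); ratios and window locations are the meaningful
#' outputs.
#'
#' @param profiles a [defect_profiles()]
#' @param temperature kelvin
#' @param prefactor optional global scale applied to P
#' @param window_mass integral fraction defining the dominant window
#' @return object of class `permeability_profile`: `xi`, `P`, `integral`,
#'   `window` (c(lo, hi)), `temperature`
#' @export
permeability_profile <- function(profiles, temperature = 296.15,
                                 prefactor = 1, window_mass = 0.9) {
  stopifnot(inherits(profiles, "defect_profiles"), temperature > 0)
  beta <- 1 / (phys_constants$R * temperature / 1000)  # mol/kJ
  P <- prefactor * profiles$flux * exp(-beta * profiles$dG)
  xi <- profiles$xi
  seg <- diff(xi) * (head(P, -1) + tail(P, -1)) / 2
  integral <- sum(seg)
  window <- c(min(xi), max(xi))
  if (integral > 0) {
    # smallest contiguous run of segments holding >= window_mass of the mass
    n <- length(seg)
    best <- c(1L, n)
    best_len <- xi[n + 1] - xi[1]
    cs <- c(0, cumsum(seg))
    for (i in seq_len(n)) {
      j <- which(cs[(i + 1):(n + 1)] - cs[i] >= window_mass * integral)
      if (length(j)) {
        jj <- i + j[1] - 1L
        len <- xi[jj + 1] - xi[i]
        if (len < best_len) {
          best_len <- len
          best <- c(i, jj)
        }
      }
    }
    window <- c(xi[best[1]], xi[best[2] + 1L])
  }
  structure(list(xi = xi, P = P, integral = integral, window = window,
                 temperature = temperature, label = profiles$label),
            class = "permeability_profile")
}

#' @export
print.permeability_profile <- function(x, ...) {
  cat(sprintf(
    "Permeability profile '%s': integral = %.4g (rel.), dominant window xi = [%.2f, %.2f]\n",
    x$label, x$integral, x$window[1], x$window[2]))
  invisible(x)
}

#' Conductance of water needles versus chain coordinate
#'
#' Fits each per-xi I-V record with [fit_iv()] and reports the conductance
#' sequence plus a monotonicity summary (larger defects conduct more).
#'
#' @param iv_per_xi named or unnamed list of [iv_record()]s, ordered by xi
#' @param xi optional xi values (defaults to the sequence index)
#' @return data.frame (class `needle_conductance`) with `xi`, `G_S`, `r2`,
#'   and attribute `monotone_increasing`
#' @export
needle_conductance <- function(iv_per_xi, xi = seq_along(iv_per_xi)) {
  stopifnot(is.list(iv_per_xi), length(iv_per_xi) >= 1,
            length(xi) == length(iv_per_xi))
  fits <- lapply(iv_per_xi, fit_iv)
  out <- data.frame(xi = xi,
                    G_S = vapply(fits, function(f) f$G, numeric(1)),
                    r2 = vapply(fits, function(f) f$r2, numeric(1)))
  attr(out, "monotone_increasing") <- !is.unsorted(out$G_S)
  class(out) <- c("needle_conductance", "data.frame")
  out
}
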