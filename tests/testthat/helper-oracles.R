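# Independent numerical oracles used to cross-check closed-form results.

# Bisection inversion of the Goldman reversal relation: finds r such that
# goldman_reversal(r, cond) = V_m without using the algebraic inverse.
goldman_bisect <- function(V_m, cond, lo = 1e-8, hi = 1e12, tol = 1e-14) {
  f <- function(r) goldman_reversal(r, cond) - V_m
  stopifnot(f(lo) * f(hi) < 0)
  for (i in 1:200) {
    mid <- sqrt(lo * hi) # geometric bisection: r spans many decades
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi / lo - 1 < tol) break
  }
  sqrt(lo * hi)
}

# Finite-difference capacitor-energy oracle for the needle stabilization
# energy: discretize the membrane cross-section into columns, assign each
# column the water or membrane permittivity depending on whether it falls
# inside the needle cylinder, sum per-column parallel-plate capacitances,
# and take the energy difference 1/2 C U^2 with and without the needle.
needle_energy_fd <- function(radius_m, thickness_m, eps_w, eps_m, U,
                             n_grid = 4000) {
  half <- radius_m * 1.5
  xs <- seq(-half, half, length.out = n_grid)
  h <- xs[2] - xs[1]
  cell <- h^2
  xc <- xs + h / 2
  inside <- outer(xc^2, xc^2, "+") <= radius_m^2
  eps0 <- protonflux::phys_constants$eps0
  C_with <- sum(ifelse(inside, eps_w, eps_m)) * cell * eps0 / thickness_m
  C_without <- sum(!is.na(inside)) * cell * eps0 * eps_m / thickness_m
  dE_J <- 0.5 * (C_with - C_without) * U^2
  dE_J * protonflux::phys_constants$N_A / 1000 # kJ/mol
}

# Trapezoidal integral of a permeability profile (independent of the
# package accessor).
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
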