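test_that("physical constants are internally consistent", {
  expect_equal(phys_constants$R,
               phys_constants$k_B * phys_constants$N_A,
               tolerance = 1e-6)
  expect_equal(phys_constants$F,
               phys_constants$e * phys_constants$N_A,
               tolerance = 1e-6)
})

test_that("proton concentration follows the ideal 10^-pH law", {
  expect_equal(proton_concentration(7), 1e-7)
  expect_equal(proton_concentration(4.1), 7.943e-5, tolerance = 1e-4)
  expect_equal(proton_concentration(7.3), 5.012e-8, tolerance = 1e-4)
  expect_error(proton_concentration(-1), "pH")
  expect_error(proton_concentration(14.5), "pH")
})

test_that("Goldman reversal potential: symmetry, Nernst limit, sign", {
  sym <- ion_conditions(pH_bottom = 7.3, pH_top = 7.3,
                        cl_bottom = 0.05, cl_top = 0.05)
  for (r in c(0.01, 1, 748)) expect_equal(goldman_reversal(r, sym), 0)

  cond <- ion_conditions() # acid on bottom, r > 1 gives V_m > 0
  expect_gt(goldman_reversal(748, cond), 0)
  # r -> Inf limit is the proton Nernst potential (RT/F) ln(10^3.2)
  vt <- thermal_voltage(296.15)
  expect_equal(goldman_reversal(Inf, cond), vt * log(10^3.2),
               tolerance = 1e-12)
  expect_equal(vt * log(10^3.2), 0.188, tolerance = 0.01)
  # r = 748 reproduces ~15 mV under the standard conditions
  expect_equal(goldman_reversal(748, cond), 0.015, tolerance = 0.01)
})

test_that("permeability ratio inversion matches the bisection oracle", {
  cond <- ion_conditions()
  for (vm in c(0.002, 0.005, 0.015, 0.05)) {
    r_closed <- permeability_ratio_from_reversal(vm, cond)
    r_bisect <- goldman_bisect(vm, cond)
    expect_equal(r_closed, r_bisect, tolerance = 1e-9)
  }
  # paper-condition checks: both measured reversal potentials give r > 50
  expect_gt(permeability_ratio_from_reversal(0.015, cond), 50)
  r2 <- permeability_ratio_from_reversal(0.002, cond)
  expect_gt(r2, 50)
  expect_equal(r2, 201, tolerance = 0.01)
})

test_that("goldman_reversal and its inversion are mutual inverses", {
  cond <- ion_conditions()
  for (r in 10^seq(-3, 6, by = 1)) {
    vm <- goldman_reversal(r, cond)
    expect_equal(permeability_ratio_from_reversal(vm, cond), r,
                 tolerance = 1e-9)
  }
})

test_that("inversion rejects ill-posed and unattainable inputs", {
  sym <- ion_conditions(pH_bottom = 7.3, pH_top = 7.3,
                        cl_bottom = 0.05, cl_top = 0.05)
  expect_error(permeability_ratio_from_reversal(0, sym), "ill-posed")
  cond <- ion_conditions()
  lim <- reversal_limits(cond)
  expect_error(permeability_ratio_from_reversal(lim[2] + 0.01, cond),
               "no solution")
  expect_error(permeability_ratio_from_reversal(lim[1] - 0.01, cond),
               "no solution")
})

test_that("goldman_reversal is monotone increasing in r with acid on bottom", {
  cond <- ion_conditions()
  r <- 10^seq(-3, 6, length.out = 40)
  v <- vapply(r, goldman_reversal, numeric(1), cond = cond)
  expect_true(all(diff(v) > 0))
})

test_that("GHK current: Ohmic limit, oddness, linearity in P", {
  sym <- ion_conditions(pH_bottom = 5, pH_top = 5,
                        cl_bottom = 0.05, cl_top = 0.05)
  P <- 1e-5; A <- 1e-4
  G <- ghk_ohmic_conductance(P, proton_concentration(5), A,
                             temperature = sym$temperature)
  u <- 1e-6
  expect_equal(ghk_current(P, u, sym, A) / u, G, tolerance = 1e-4)
  # odd in U at symmetric concentrations
  for (U in c(0.01, 0.03, 0.06)) {
    expect_equal(ghk_current(P, U, sym, A),
                 -ghk_current(P, -U, sym, A), tolerance = 1e-12)
  }
  # linear in P
  cond <- ion_conditions()
  expect_equal(ghk_current(2 * P, -0.06, cond, A),
               2 * ghk_current(P, -0.06, cond, A), tolerance = 1e-12)
})

test_that("GHK permeability inversion reproduces the measured value", {
  cond <- ion_conditions()
  A <- 9503e-8 # 9503 um^2 in cm^2
  P <- permeability_from_current(-7.6e-12, -0.06, cond, A)
  expect_equal(P$value, 3.7e-6, tolerance = 0.15)
  # the inversion is exact: round trip to machine precision
  expect_equal(ghk_current(P$value, -0.06, cond, A), -7.6e-12,
               tolerance = 1e-12)
  # stable across the plausible room-temperature range
  for (temp in c(293, 298)) {
    ct <- ion_conditions(temperature = temp)
    expect_equal(permeability_from_current(-7.6e-12, -0.06, ct, A)$value,
                 3.7e-6, tolerance = 0.15)
  }
  # derived check at the smaller current
  expect_equal(permeability_from_current(-4.6e-12, -0.06, cond, A)$value,
               2.43e-6, tolerance = 0.01)
})

test_that("GHK current/permeability round-trip over a grid", {
  cond <- ion_conditions()
  A <- 9503e-8
  for (P in c(1e-7, 3.7e-6, 1e-4)) {
    for (U in c(-0.06, -0.01, 0.025)) {
      i <- ghk_current(P, U, cond, A)
      expect_equal(permeability_from_current(i, U, cond, A)$value, P,
                   tolerance = 1e-9)
    }
  }
  expect_error(permeability_from_current(7.6e-12, -0.06, cond, A),
               "inconsistent")
})

test_that("flux-to-permeability conversion reproduces both membranes", {
  A <- 9503e-8
  expect_equal(permeability_from_flux(7.5e6, A)$value, 1.7e-6,
               tolerance = 0.10)
  expect_equal(permeability_from_flux(0.8e6, A)$value, 0.2e-6,
               tolerance = 0.15)
  # linearity
  expect_equal(permeability_from_flux(1.5e7, A)$value,
               2 * permeability_from_flux(7.5e6, A)$value,
               tolerance = 1e-12)
  expect_error(permeability_from_flux(7.5e6, A, delta_c_mol_per_L = 0),
               "gradient")
})

test_that("unstirred-layer bound and transported moles", {
  expect_equal(unstirred_layer_permeability(5e-6, 200e-4), 2.5e-4)
  expect_equal(unstirred_layer_permeability(0, 200e-4), 0)
  expect_equal(unstirred_layer_permeability(5e-6, 1e9), 5e-15)

  # one elementary charge per second for one second = 1/N_A moles
  expect_equal(transported_moles(phys_constants$e, 1),
               1 / phys_constants$N_A, tolerance = 1e-9)
  expect_equal(transported_moles(0, 3600), 0)
  # trapezoidal trace integration equals constant-current arithmetic
  tt <- seq(0, 3600, by = 60)
  expect_equal(transported_moles(rep(2.54e-12, length(tt)), times = tt),
               transported_moles(2.54e-12, 3600), tolerance = 1e-12)
})

test_that("I-V fitting recovers exact lines and flags degenerate sweeps", {
  v <- seq(-0.06, 0.06, length.out = 11)
  G <- 2.3e-9; Vr <- 0.015
  fit <- fit_iv(iv_record(v, G * (v - Vr)), area_cm2 = 9503e-8)
  expect_equal(fit$G, G, tolerance = 1e-12)
  expect_equal(fit$V_m, Vr, tolerance = 1e-9)
  expect_equal(fit$specific_conductance, G / 9503e-8, tolerance = 1e-12)
  # flat zero current: conductance zero, reversal potential undefined
  flat <- fit_iv(iv_record(v, rep(0, 11)))
  expect_equal(flat$G, 0)
  expect_false(flat$vm_defined)
  expect_error(iv_record(rep(0.01, 3), 1:3), "increasing")
})

test_that("noisy I-V sweeps recover the reversal potential within 3 sigma", {
  v <- seq(-0.06, 0.06, length.out = 11)
  G <- 2e-9; Vr <- 0.015
  sigma_I <- 0.02 * diff(range(G * (v - Vr)))
  # analytic standard error of -b/a for an OLS line, evaluated at truth
  n <- length(v)
  sxx <- sum((v - mean(v))^2)
  se_vr <- (sigma_I / G) * sqrt(1 / n + (Vr - mean(v))^2 / sxx)
  err <- vapply(1:200, function(s) {
    g <- gen_iv(G, Vr, n_points = 11, noise_sigma = sigma_I, seed = s)
    fit_iv(g$iv)$V_m - Vr
  }, numeric(1))
  expect_gt(mean(abs(err) < 3 * se_vr), 0.95)
})

test_that("GCS surface potential: symmetry, monotonicity, linearized limit", {
  p <- gcs_params(0.060)
  expect_equal(gcs_surface_potential(0, p), 0)
  sig <- seq(-0.2, 0.2, length.out = 41)
  psi <- gcs_surface_potential(sig, p)
  expect_true(all(diff(psi) > 0))
  expect_equal(psi, -rev(psi), tolerance = 1e-12) # odd
  # Debye-Hueckel closed form within 1% for |psi| < 10 mV
  small <- abs(psi) < 0.010
  expect_equal(gcs_surface_potential(sig[small], p),
               gcs_linearized_potential(sig[small], p), tolerance = 0.01)
})

test_that("a Stern layer is required for ~350 mV at 60 mM ionic strength", {
  p_nostern <- gcs_params(0.060)
  p_stern <- gcs_params(0.060, stern_capacitance = 1)
  # with-Stern potential exceeds the diffuse-only potential for equal sigma
  for (sig in c(0.01, 0.05, 0.2)) {
    expect_gt(gcs_surface_potential(sig, p_stern),
              gcs_surface_potential(sig, p_nostern))
  }
  # without a Stern layer, 350 mV needs an absurd charge density (the
  # fully charged PS leaflet is well below 1 C/m^2)
  expect_gt(gcs_charge_for_potential(0.35, p_nostern), 1)
  # with a ~1 F/m^2 Stern layer it is reachable at plausible densities
  expect_lt(gcs_charge_for_potential(0.35, p_stern), 0.5)
})
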