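test_that("needle stabilization energy: magnitude, scaling, zero field", {
  geom <- needle_geometry(radius_m = 3e-10, thickness_m = 4e-9,
                          eps_w = 80, eps_m = 2.1)
  expect_equal(needle_stabilization_energy(geom, 0), 0)
  e300 <- needle_stabilization_energy(geom, 0.3)
  # the reported magnitude is ~1 kJ/mol; agree within a factor of 2
  expect_gt(e300, 0.5)
  expect_lt(e300, 2)
  # quadratic in U and in r
  expect_equal(needle_stabilization_energy(geom, 0.6), 4 * e300,
               tolerance = 1e-12)
  geom2 <- needle_geometry(radius_m = 6e-10, thickness_m = 4e-9,
                           eps_w = 80, eps_m = 2.1)
  expect_equal(needle_stabilization_energy(geom2, 0.3), 4 * e300,
               tolerance = 1e-12)
})

test_that("analytic needle energy matches the finite-difference oracle", {
  for (r in c(1e-10, 3e-10)) {
    geom <- needle_geometry(radius_m = r, thickness_m = 4e-9,
                            eps_w = 80, eps_m = 2.1)
    analytic <- needle_stabilization_energy(geom, 0.3)
    fd <- needle_energy_fd(r, 4e-9, 80, 2.1, 0.3)
    expect_equal(analytic, fd, tolerance = 0.05)
  }
})

test_that("flat free energy with constant flux gives a flat profile", {
  xi <- seq(0.1, 1, by = 0.02)
  prof <- defect_profiles(xi, rep(0, length(xi)), rep(1e6, length(xi)))
  pp <- permeability_profile(prof)
  expect_true(all(abs(pp$P - pp$P[1]) < 1e-9))
  # dominant window spans (almost) the whole grid for a flat profile
  expect_lt(pp$window[1], 0.2)
  expect_gt(pp$window[2], 0.9)
})

test_that("a 15 kJ/mol barrier offset scales integrated permeability by exp(beta ddG)", {
  a <- gen_defect_profiles(ddG_offset = 0)$profiles
  b <- gen_defect_profiles(ddG_offset = 15)$profiles
  pa <- permeability_profile(a)
  pb <- permeability_profile(b)
  beta <- 1000 / (phys_constants$R * 296.15)
  expect_equal(pa$integral / pb$integral, exp(beta * 15), tolerance = 0.05)
  # two orders of magnitude, as between the two membrane chemistries
  expect_gt(pa$integral / pb$integral, 100)
})

test_that("permeation concentrates in the water-needle window", {
  prof <- gen_defect_profiles()$profiles
  pp <- permeability_profile(prof)
  # flux turns on near 0.74 and the free energy rises steeply past ~0.85:
  # the dominant window sits in the needle regime and brackets xi ~ 0.74
  expect_gte(pp$window[1], 0.60 - 1e-9)
  expect_lte(pp$window[2], 0.92)
  expect_true(pp$window[1] <= 0.74 && pp$window[2] >= 0.74)
  # integral agrees with an independent trapezoid
  beta <- 1000 / (phys_constants$R * 296.15)
  expect_equal(pp$integral,
               trapz(prof$xi, prof$flux * exp(-beta * prof$dG)),
               tolerance = 1e-12)
})

test_that("profiles are scale-invariant under constant dG offsets", {
  base <- gen_defect_profiles()$profiles
  shifted <- defect_profiles(base$xi, base$dG, base$flux)
  shifted$dG <- base$dG # same shape; emulate offset through prefactor
  beta <- 1000 / (phys_constants$R * 296.15)
  p0 <- permeability_profile(base)
  # adding a constant c to dG multiplies P by exp(-beta c) globally:
  # normalized shapes are identical
  pc <- permeability_profile(
    structure(list(xi = base$xi, dG = base$dG + 7, flux = base$flux,
                   voltage_V = 0.3, label = ""),
              class = "defect_profiles"))
  expect_equal(pc$P / pc$integral, p0$P / p0$integral, tolerance = 1e-9)
  expect_equal(pc$window, p0$window)
})

test_that("lowering any dG value increases the integrated permeability", {
  base <- gen_defect_profiles()$profiles
  p0 <- permeability_profile(base)$integral
  for (k in c(5, 25, 40)) {
    mod <- base
    mod$dG[k] <- max(mod$dG[k] - 3, 0)
    if (k == 1) mod$dG <- mod$dG - mod$dG[1]
    expect_gte(permeability_profile(mod)$integral, p0)
  }
})

test_that("needle conductance tracks the generator's G(xi) ordering", {
  xi <- seq(0.62, 0.96, by = 0.02)
  G <- 1e-12 * exp(8 * (xi - 0.62)) # increasing conductance family
  ivs <- lapply(seq_along(xi), function(k) {
    gen_iv(G[k], V_rev = 0, n_points = 7, noise_sigma = 0, seed = k)$iv
  })
  nc <- needle_conductance(ivs, xi = xi)
  expect_true(attr(nc, "monotone_increasing"))
  expect_equal(nc$G_S, G, tolerance = 1e-9)
  # zero-current family gives all-zero conductance
  ivs0 <- lapply(1:3, function(k) iv_record(c(-0.1, 0, 0.1), rep(0, 3)))
  expect_equal(needle_conductance(ivs0)$G_S, rep(0, 3))
  # single-point records are rejected
  expect_error(iv_record(0.1, 1e-12))
})

test_that("profile CSV round trip preserves the tables", {
  prof <- gen_defect_profiles(ddG_offset = 3)$profiles
  path <- tempfile(fileext = ".csv")
  write_profiles_csv(prof, path)
  back <- read_profiles_csv(path)
  expect_equal(back$xi, prof$xi)
  expect_equal(back$dG, prof$dG, tolerance = 1e-9)
  expect_equal(back$flux, prof$flux, tolerance = 1e-9)
})
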