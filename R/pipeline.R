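#' Run configuration for the analysis pipeline
#'
#' One validated container for all pipeline inputs and constants. Defaults
#' match the acid-on-bottom study conditions: pH 4.1/7.3, Cl 61/50 mM,
#' room temperature, a 55 um aperture, the 2.1/4 nm hydrophobic-core
#' capacitor, and the default segmentation constants (k_sigma = 3,
#' min_area_px = 4).
#'
#' @param iv_files character vector of I-V CSV paths (see [read_iv_csv()])
#' @param stack_file TIFF stack path (see [read_stack_tiff()]), or `NULL`
#' @param profile_files character vector of defect-profile CSV paths
#' @param conditions an [ion_conditions()]
#' @param radius_um membrane aperture radius (area = pi r^2)
#' @param capacitor a [capacitor_model()]
#' @param cal an [sh_calibration()]
#' @param k_sigma,min_area_px segmentation constants
#' @param roi_size_um ROI edge for the decay map
#' @param i_proton_A,U_bias_V proton-induced current (A) and external bias
#'   (V) for the GHK permeability, or `NULL` to skip
#' @param duration_s integration time for transported moles
#' @param i_zero_bias_A zero-bias current (A) for transported moles, or
#'   `NULL`
#' @param temperature kelvin (overrides `conditions$temperature` when given)
#' @param seed RNG seed recorded in the provenance block
#' @return object of class `run_config`
#' @export
run_config <- function(iv_files = character(), stack_file = NULL,
                       profile_files = character(),
                       conditions = ion_conditions(),
                       radius_um = 55,
                       capacitor = capacitor_model(),
                       cal = sh_calibration(chi3_prime = 1,
                                            intensity_scale = 2e4),
                       k_sigma = 3, min_area_px = 4, roi_size_um = 4.5,
                       i_proton_A = NULL, U_bias_V = NULL,
                       duration_s = 3600, i_zero_bias_A = NULL,
                       temperature = NULL, seed = 1L) {
  stopifnot(inherits(conditions, "ion_conditions"), radius_um > 0,
            inherits(capacitor, "capacitor_model"),
            inherits(cal, "sh_calibration"),
            k_sigma > 0, min_area_px >= 1, roi_size_um > 0, duration_s > 0)
  if (!is.null(temperature)) conditions$temperature <- temperature
  structure(list(
    iv_files = iv_files, stack_file = stack_file,
    profile_files = profile_files, conditions = conditions,
    radius_um = radius_um, area_um2 = membrane_area(radius_um),
    area_cm2 = membrane_area(radius_um) * 1e-8,
    capacitor = capacitor, cal = cal,
    k_sigma = k_sigma, min_area_px = min_area_px,
    roi_size_um = roi_size_um,
    i_proton_A = i_proton_A, U_bias_V = U_bias_V,
    duration_s = duration_s, i_zero_bias_A = i_zero_bias_A,
    seed = seed), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields of [run_config()] plus nested `conditions:`, `capacitor:`
#' (`eps`, `d_nm`) and `calibration:` (`chi3_prime`, `intensity_scale`,
#' `chi2_effective`) blocks. Paths are resolved relative to the YAML file.
#'
#' @param path YAML file
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(p)
    vapply(p, function(x) {
      if (file.exists(x)) x else file.path(base, x)
    }, character(1), USE.NAMES = FALSE)
  }
  cond <- do.call(ion_conditions, y$conditions %||% list())
  cap <- if (!is.null(y$capacitor)) {
    capacitor_model(eps = y$capacitor$eps %||% 2.1,
                    d_m = (y$capacitor$d_nm %||% 4) * 1e-9)
  } else capacitor_model()
  cal <- if (!is.null(y$calibration)) {
    sh_calibration(chi3_prime = y$calibration$chi3_prime %||% 1,
                   intensity_scale = y$calibration$intensity_scale %||% 2e4,
                   chi2_effective = y$calibration$chi2_effective %||% 0)
  } else sh_calibration(chi3_prime = 1, intensity_scale = 2e4)
  run_config(
    iv_files = rel(y$iv_files) %||% character(),
    stack_file = if (is.null(y$stack_file)) NULL else rel(y$stack_file),
    profile_files = rel(y$profile_files) %||% character(),
    conditions = cond, radius_um = y$radius_um %||% 55,
    capacitor = cap, cal = cal,
    k_sigma = y$k_sigma %||% 3, min_area_px = y$min_area_px %||% 4,
    roi_size_um = y$roi_size_um %||% 4.5,
    i_proton_A = y$i_proton_A, U_bias_V = y$U_bias_V,
    duration_s = y$duration_s %||% 3600,
    i_zero_bias_A = y$i_zero_bias_A,
    temperature = y$temperature, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conductivity analysis: I-V fits, permeability ratio, GHK permeability
#'
#' Fits every supplied I-V sweep, selects the sweep with the maximal fitted
#' conductance, inverts the Goldman equation at its reversal potential for
#' the H+/Cl- permeability ratio, computes the GHK proton permeability from
#' the configured proton-induced current and bias, and integrates the
#' zero-bias current into transported moles. Symmetric conditions leave the
#' permeability ratio undefined (flagged); the run continues.
#'
#' @param config a [run_config()]
#' @param iv_records optional list of [iv_record()]s used instead of
#'   reading `config$iv_files`
#' @return a report section (list, class `conductivity_report`)
#' @export
run_conductivity_analysis <- function(config, iv_records = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(iv_records)) {
    if (!length(config$iv_files)) stop("no I-V files configured")
    iv_records <- lapply(config$iv_files, read_iv_csv)
  }
  if (!length(iv_records)) stop("no I-V records supplied")
  fits <- lapply(iv_records, fit_iv, area_cm2 = config$area_cm2)
  G <- vapply(fits, function(f) f$G, numeric(1))
  best <- which.max(G)
  sel <- fits[[best]]
  cond <- config$conditions
  symmetric <- cond$h_bottom == cond$h_top && cond$cl_bottom == cond$cl_top
  ratio <- NA_real_; ratio_flag <- ""
  if (symmetric) {
    ratio_flag <- "symmetric conditions: permeability ratio undefined"
  } else if (!sel$vm_defined) {
    ratio_flag <- "reversal potential undefined: permeability ratio skipped"
  } else {
    ratio <- tryCatch(permeability_ratio_from_reversal(sel$V_m, cond),
                      error = function(e) NA_real_)
    if (is.na(ratio)) ratio_flag <- "V_m outside attainable Goldman interval"
  }
  P_ghk <- NULL
  if (!is.null(config$i_proton_A) && !is.null(config$U_bias_V)) {
    P_ghk <- permeability_from_current(config$i_proton_A, config$U_bias_V,
                                       cond, config$area_cm2)
  }
  moles <- if (!is.null(config$i_zero_bias_A)) {
    transported_moles(config$i_zero_bias_A, config$duration_s)
  } else NULL
  structure(list(
    fits = fits, selected = best, G_S = sel$G, V_m = sel$V_m,
    specific_conductance_S_per_cm2 = sel$specific_conductance,
    permeability_ratio = ratio, ratio_flag = ratio_flag,
    P_ghk = P_ghk, transported_moles = moles,
    provenance = list(area_um2 = config$area_um2,
                      radius_um = config$radius_um,
                      temperature_K = cond$temperature,
                      duration_s = config$duration_s,
                      n_sweeps = length(fits), seed = config$seed)),
    class = "conductivity_report")
}

#' @export
print.conductivity_report <- function(x, ...) {
  cat("Conductivity analysis\n")
  cat(sprintf("  %d sweep(s); selected #%d: G = %.4g S (%.4g S/cm^2), V_m = %.4g V\n",
              x$provenance$n_sweeps, x$selected, x$G_S,
              x$specific_conductance_S_per_cm2, x$V_m))
  if (is.finite(x$permeability_ratio)) {
    cat(sprintf("  P_H/P_Cl = %.3g\n", x$permeability_ratio))
  } else cat("  P_H/P_Cl:", x$ratio_flag, "\n")
  if (!is.null(x$P_ghk)) {
    cat(sprintf("  GHK proton permeability = %.3g cm/s\n", x$P_ghk$value))
  }
  if (!is.null(x$transported_moles)) {
    cat(sprintf("  transported H+ over %g s: %.3g mol\n",
                x$provenance$duration_s %||% NA, x$transported_moles))
  }
  invisible(x)
}

#' Imaging analysis: segmentation, histograms, decay maps, flux, retention
#'
#' Runs the SH image chain on a stack: per-frame domain segmentation at the
#' envelope-peak window, occurrence histogram with Gaussian fit, windowed
#' mean-potential series, whole-field exponential decay fit, per-ROI
#' tau/flux maps, the flux-based permeability, capacitor-model charge
#' accounting over the peak-window domains, and (when transported moles from
#' a conductivity run are supplied) the interface retention fraction.
#'
#' @param config a [run_config()]
#' @param stack optional [sh_stack()] used instead of reading
#'   `config$stack_file`; its metadata must contain `t_acid_s` and
#'   `frame_windows`
#' @param conductivity_moles optional transported moles from
#'   [run_conductivity_analysis()]
#' @param verbose narrate pipeline stages with counts
#' @return a report section (list, class `imaging_report`)
#' @export
run_imaging_analysis <- function(config, stack = NULL,
                                 conductivity_moles = NULL,
                                 verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(stack)) {
    if (is.null(config$stack_file)) stop("no stack configured")
    stack <- read_stack_tiff(config$stack_file)
  }
  if (!prod(dim(stack$frames))) stop("empty stack")
  say <- function(...) if (verbose) message(sprintf(...))
  t_acid_s <- stack$metadata$t_acid_s
  if (is.null(t_acid_s)) {
    warning("missing HCl-addition timestamp: decay fitting skipped")
  }
  fw <- stack$metadata$frame_windows
  if (is.null(fw)) fw <- list(seq_len(dim(stack$frames)[3]))
  wt_min <- vapply(fw, function(f) mean(stack$times_s[f]) / 60, numeric(1))
  say("stack: %d frames in %d windows", dim(stack$frames)[3], length(fw))

  # decay kinetics are fitted on the background-subtracted intensity: its
  # noise stays zero-mean (no square-root rectification), and the quadratic
  # SH response makes intensity decay at twice the potential rate, so
  # fitted constants are doubled on reporting
  cube <- window_mean_cube(stack, fw, mode = "intensity_excess")
  field_series <- apply(cube, 3, mean)

  # segment the envelope-peak window for the occurrence histogram
  peak_w <- which.max(field_series)
  catalog <- segment_stack(stack, frames = fw[[peak_w]],
                           k_sigma = config$k_sigma,
                           min_area_px = config$min_area_px,
                           cal = config$cal)
  say("segmentation: %d domains in peak window %d", nrow(catalog), peak_w)
  histogram <- if (nrow(catalog)) {
    domain_occurrence_histogram(catalog)
  } else NULL

  # windowed series of area-weighted mean domain potential
  all_catalog <- segment_stack(stack, k_sigma = config$k_sigma,
                               min_area_px = config$min_area_px,
                               cal = config$cal)
  series <- if (nrow(all_catalog)) {
    mean_domain_potential_series(all_catalog, fw, wt_min)
  } else NULL

  whole_fit <- NULL; tmap <- NULL; flux <- NA_real_; P_flux <- NULL
  whole_tau <- NA_real_
  if (!is.null(t_acid_s)) {
    whole_fit <- fit_exponential_decay(wt_min, field_series)
    whole_tau <- 2 * whole_fit$tau_min  # intensity -> potential decay
    roi_px <- max(1L, round(config$roi_size_um / stack$pixel_size_um))
    # the decay onset is global (set by the acid addition), so the ROI fits
    # share the whole-field t_start; only tau varies spatially
    tmap <- roi_tau_map(cube, wt_min, roi_px, t_start = whole_fit$t_start,
                        tau_scale = 2, baseline = 0)
    say("decay: whole-field tau = %.3g min; %d/%d ROIs fitted",
        whole_tau, tmap$n_fitted, length(tmap$tau))
    flux <- tau_to_flux(whole_tau)
    P_flux <- permeability_from_flux(flux, config$area_cm2,
                                     cond = config$conditions)
  }

  # capacitor charge accounting over the peak-window domains
  accounting <- NULL; retention <- NULL
  if (nrow(catalog)) {
    sigma <- charge_density_from_potential(catalog$mean_potential_V,
                                           config$capacitor)
    accounting <- bound_protons(sigma, catalog$area_um2 * 1e-12)
    if (!is.null(conductivity_moles)) {
      retention <- interface_retention_fraction(conductivity_moles,
                                                sum(accounting$moles))
    }
  }
  structure(list(
    histogram = histogram, series = series, whole_field_fit = whole_fit,
    whole_field_tau_min = whole_tau,
    tau_map = tmap, flux_ions_per_s = flux, P_flux = P_flux,
    accounting = accounting, retention = retention,
    peak_window = peak_w, n_domains_peak = nrow(catalog),
    provenance = list(area_um2 = config$area_um2,
                      k_sigma = config$k_sigma,
                      min_area_px = config$min_area_px,
                      roi_size_um = config$roi_size_um,
                      seed = config$seed)),
    class = "imaging_report")
}

#' @export
print.imaging_report <- function(x, ...) {
  cat("Imaging analysis\n")
  if (!is.null(x$histogram)) {
    cat(sprintf("  peak-window domains: %d; potential mu = %.3g V, sigma = %.3g V\n",
                x$n_domains_peak, x$histogram$mu, x$histogram$sigma))
  }
  if (!is.null(x$whole_field_fit)) {
    cat(sprintf("  whole-field tau = %.3g min -> flux = %.3g ions/s\n",
                x$whole_field_tau_min, x$flux_ions_per_s))
  }
  if (!is.null(x$tau_map)) {
    cat(sprintf("  ROI map: %d fitted, tau = %.3g +/- %.3g min\n",
                x$tau_map$n_fitted, mean(x$tau_map$tau, na.rm = TRUE),
                stats::sd(x$tau_map$tau, na.rm = TRUE)))
  }
  if (!is.null(x$P_flux)) {
    cat(sprintf("  flux permeability = %.3g cm/s\n", x$P_flux$value))
  }
  if (!is.null(x$retention)) cat("  retention:", x$retention$text, "\n")
  invisible(x)
}

#' Needle analysis: permeability profiles, windows, stabilization energies
#'
#' Computes the Boltzmann-weighted permeability profile for each supplied
#' defect-profile table, the pairwise integrated-permeability ratios between
#' membranes, and the analytic needle stabilization energy over a grid of
#' radii and potentials.
#'
#' @param config a [run_config()]
#' @param profiles optional list of [defect_profiles()] used instead of
#'   reading `config$profile_files`
#' @param radii_m needle radii for the energy grid, m
#' @param potentials_V potentials for the energy grid, V
#' @return a report section (list, class `needle_report`)
#' @export
run_needle_analysis <- function(config, profiles = NULL,
                                radii_m = c(1e-10, 2e-10, 3e-10),
                                potentials_V = c(0.1, 0.2, 0.3)) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(profiles)) {
    if (!length(config$profile_files)) stop("no profile files configured")
    profiles <- lapply(config$profile_files, read_profiles_csv)
  }
  if (!length(profiles)) stop("no defect profiles supplied")
  temp <- config$conditions$temperature
  pp <- lapply(profiles, permeability_profile, temperature = temp)
  integrals <- vapply(pp, function(p) p$integral, numeric(1))
  ratios <- if (length(pp) >= 2) outer(integrals, integrals, "/") else NULL
  energy <- outer(radii_m, potentials_V, function(r, U) {
    mapply(function(ri, Ui) {
      needle_stabilization_energy(
        needle_geometry(radius_m = ri,
                        thickness_m = config$capacitor$d_m,
                        eps_m = config$capacitor$eps), Ui)
    }, r, U)
  })
  dimnames(energy) <- list(paste0("r_", radii_m * 1e10, "A"),
                           paste0("U_", potentials_V * 1000, "mV"))
  structure(list(profiles = pp, integrals = integrals, ratios = ratios,
                 energy_grid_kJ_per_mol = energy,
                 provenance = list(temperature_K = temp,
                                   n_profiles = length(pp),
                                   seed = config$seed)),
            class = "needle_report")
}

#' @export
print.needle_report <- function(x, ...) {
  cat("Needle analysis\n")
  for (p in x$profiles) print(p)
  if (!is.null(x$ratios) && length(x$integrals) == 2) {
    cat(sprintf("  integrated permeability ratio (1/2): %.3g\n",
                x$ratios[1, 2]))
  }
  cat("  stabilization energy grid (kJ/mol):\n")
  print(round(x$energy_grid_kJ_per_mol, 3))
  invisible(x)
}

#' Assemble and serialize a full report
#'
#' @param conductivity,imaging,needle report sections (any may be `NULL`)
#' @param config the [run_config()] used
#' @return object of class `protonflux_report`
#' @export
assemble_report <- function(conductivity = NULL, imaging = NULL,
                            needle = NULL, config) {
  structure(list(conductivity = conductivity, imaging = imaging,
                 needle = needle,
                 provenance = list(
                   seed = config$seed,
                   area_um2 = config$area_um2,
                   temperature_K = config$conditions$temperature,
                   package_version =
                     as.character(utils::packageVersion("protonflux")))),
            class = "protonflux_report")
}

#' @export
print.protonflux_report <- function(x, ...) {
  cat("== protonflux report ==\n")
  if (!is.null(x$conductivity)) print(x$conductivity)
  if (!is.null(x$imaging)) print(x$imaging)
  if (!is.null(x$needle)) print(x$needle)
  invisible(x)
}

#' Write a report to JSON
#'
#' Numbers only (fits and catalogs reduced to their summary values);
#' deterministic for a given config and seed.
#'
#' @param report a `protonflux_report`
#' @param path output path
#' @return the path, invisibly
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "protonflux_report"))
  num <- function(v) if (is.null(v)) NULL else unname(v)
  out <- list(provenance = report$provenance)
  if (!is.null(report$conductivity)) {
    cr <- report$conductivity
    out$conductivity <- list(
      G_S = cr$G_S, Vm_V = cr$V_m,
      specific_conductance_S_per_cm2 = cr$specific_conductance_S_per_cm2,
      permeability_ratio = num(cr$permeability_ratio),
      P_ghk_cm_per_s = if (!is.null(cr$P_ghk)) cr$P_ghk$value,
      transported_moles = num(cr$transported_moles))
  }
  if (!is.null(report$imaging)) {
    ir <- report$imaging
    out$imaging <- list(
      potential_mu_V = if (!is.null(ir$histogram)) ir$histogram$mu,
      potential_sigma_V = if (!is.null(ir$histogram)) ir$histogram$sigma,
      whole_field_tau_min = num(ir$whole_field_tau_min),
      flux_ions_per_s = num(ir$flux_ions_per_s),
      P_flux_cm_per_s = if (!is.null(ir$P_flux)) ir$P_flux$value,
      bound_moles = if (!is.null(ir$accounting)) sum(ir$accounting$moles),
      retention_one_out_of = if (!is.null(ir$retention)) ir$retention$X_2sf)
  }
  if (!is.null(report$needle)) {
    nr <- report$needle
    out$needle <- list(
      integrals = nr$integrals,
      windows = lapply(nr$profiles, function(p) p$window),
      energy_grid_kJ_per_mol = nr$energy_grid_kJ_per_mol)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
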