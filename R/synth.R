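#' Specification of a synthetic SH image stack
#'
#' The defaults encode the standard acid-on-bottom experiment as the
#' generators emulate it: a 45 um field imaged at 0.5 um/px (90 x 90
#' pixels), observation windows of 20 one-second frames spaced 4 minutes
#' apart over ~2.6 h, acid added at t = 10 min, transient bright domains
#' (lifetime one frame, no interframe correlation) with potentials drawn
#' from N(0.12, 0.05) V, and a spatially varying decay-constant field drawn
#' from N(42, 24) min truncated above 5 min on a grid of 4.5 um tiles.
#'
#' @param field_um field of view edge, um
#' @param pixel_um pixel size, um
#' @param n_windows number of observation windows
#' @param frames_per_window frames per window (1 s frame period)
#' @param window_spacing_min time between window starts, minutes
#' @param t_acid_min acid-addition time, minutes
#' @param rise_min envelope rise time after acid addition, minutes
#' @param birth_rate expected domain births per frame (Poisson)
#' @param radius_median_um,radius_sdlog lognormal domain radius parameters
#' @param potential_mu_V,potential_sigma_V Gaussian domain potential
#'   parameters (V), truncated > 0
#' @param tau_mu_min,tau_sigma_min,tau_trunc_min Gaussian decay-constant
#'   field parameters (minutes), truncated above `tau_trunc_min`
#' @param tau_tile_um edge of the square tiles on which the tau field is
#'   piecewise constant
#' @param cal [sh_calibration()] used as the forward intensity model
#' @param baseline_counts dark/background level added to every pixel
#' @param read_noise_sd Gaussian read noise (counts); shot noise is Poisson
#' @param seed RNG seed
#' @return object of class `sh_stack_spec`
#' @export
sh_stack_spec <- function(field_um = 45, pixel_um = 0.5,
                          n_windows = 60, frames_per_window = 20,
                          window_spacing_min = 2.5, t_acid_min = 10,
                          rise_min = 2, birth_rate = 60,
                          radius_median_um = 1, radius_sdlog = 0.3,
                          potential_mu_V = 0.12, potential_sigma_V = 0.05,
                          tau_mu_min = 42, tau_sigma_min = 24,
                          tau_trunc_min = 5, tau_tile_um = 4.5,
                          cal = sh_calibration(chi3_prime = 1,
                                               intensity_scale = 2e4),
                          baseline_counts = 20, read_noise_sd = 2,
                          seed = 1L) {
  stopifnot(field_um > 0, pixel_um > 0, n_windows >= 1,
            frames_per_window >= 1, birth_rate >= 0,
            tau_trunc_min > 0, tau_sigma_min > 0,
            baseline_counts >= 0, read_noise_sd >= 0)
  structure(as.list(environment()), class = "sh_stack_spec")
}

#' Rise-then-decay potential envelope
#'
#' The temporal envelope the generator applies to domain potentials: zero
#' before the acid addition, then `(1 - exp(-dt/rise)) * exp(-dt/tau)`
#' divided by `norm`. [gen_sh_stack()] sets `norm` so the envelope of a
#' mean-tau pixel peaks at 1. Vectorized over `t_min` and `tau` (recycled
#' to a common length).
#'
#' @param t_min time, minutes
#' @param t_acid acid-addition time, minutes
#' @param rise rise time constant, minutes
#' @param tau decay constant, minutes
#' @param norm peak normalization
#' @return envelope value(s)
#' @export
sh_envelope <- function(t_min, t_acid, rise, tau, norm = 1) {
  n <- max(length(t_min), length(tau))
  t <- rep_len(t_min, n)
  tv <- rep_len(tau, n)
  dt <- pmax(t - t_acid, 0)
  val <- (1 - exp(-dt / rise)) * exp(-dt / tv) / norm
  val[t <= t_acid] <- 0
  val
}

sh_envelope_norm <- function(t_acid, rise, tau) {
  tpk <- rise * log(1 + tau / rise)
  (1 - exp(-tpk / rise)) * exp(-tpk / tau)
}

#' Generate a synthetic SH stack with ground truth
#'
#' Domains appear and disappear independently in each frame (no interframe
#' correlation); their base potentials are Gaussian; the realized potential
#' is the base value scaled by a rise-then-exponential-decay envelope whose
#' decay constant varies over the field (piecewise-constant tau tiles).
#' Intensities follow the quadratic SH forward model of the supplied
#' calibration; Poisson shot noise plus Gaussian read noise is applied
#' last. Deterministic under a fixed seed.
#'
#' @param spec an [sh_stack_spec()]
#' @return list with `stack` (an [sh_stack()]) and `truth` (a list:
#'   `domains` data.frame with per-domain frame, center, radius, base and
#'   realized potential; `tau_field` per-pixel matrix; `tau_tiles` per-tile
#'   matrix; `envelope` parameters; `frame_windows`; `window_times_min`;
#'   `spec`)
#' @export
gen_sh_stack <- function(spec = sh_stack_spec()) {
  stopifnot(inherits(spec, "sh_stack_spec"))
  set.seed(spec$seed)
  npx <- round(spec$field_um / spec$pixel_um)
  nframes <- spec$n_windows * spec$frames_per_window
  frame_windows <- split(seq_len(nframes),
                         rep(seq_len(spec$n_windows),
                             each = spec$frames_per_window))
  t_frame_min <- rep((seq_len(spec$n_windows) - 1) * spec$window_spacing_min,
                     each = spec$frames_per_window) +
    rep(seq_len(spec$frames_per_window) - 1, spec$n_windows) / 60
  window_times_min <- vapply(frame_windows,
                             function(fr) mean(t_frame_min[fr]), numeric(1))

  # piecewise-constant truncated-Gaussian tau field on square tiles
  tile_px <- max(1L, round(spec$tau_tile_um / spec$pixel_um))
  ntile <- ceiling(npx / tile_px)
  tau_tiles <- matrix(0, ntile, ntile)
  for (i in seq_len(ntile * ntile)) {
    repeat {
      v <- stats::rnorm(1, spec$tau_mu_min, spec$tau_sigma_min)
      if (v > spec$tau_trunc_min) break
    }
    tau_tiles[i] <- v
  }
  tau_field <- tau_tiles[cbind(
    rep(pmin((seq_len(npx) - 1L) %/% tile_px + 1L, ntile), npx),
    rep(pmin((seq_len(npx) - 1L) %/% tile_px + 1L, ntile), each = npx))]
  tau_field <- matrix(tau_field, npx, npx)

  norm <- sh_envelope_norm(spec$t_acid_min, spec$rise_min, spec$tau_mu_min)

  frames <- array(0, dim = c(npx, npx, nframes))
  dom_list <- vector("list", nframes)
  for (f in seq_len(nframes)) {
    n_dom <- stats::rpois(1, spec$birth_rate)
    pot_field <- matrix(0, npx, npx)
    if (n_dom > 0) {
      cx <- stats::runif(n_dom, 1, npx)
      cy <- stats::runif(n_dom, 1, npx)
      rad_px <- stats::rlnorm(n_dom, log(spec$radius_median_um),
                              spec$radius_sdlog) / spec$pixel_um
      base_pot <- abs(stats::rnorm(n_dom, spec$potential_mu_V,
                                   spec$potential_sigma_V))
      for (k in seq_len(n_dom)) {
        r <- rad_px[k]
        ys <- max(1L, floor(cy[k] - r)):min(npx, ceiling(cy[k] + r))
        xs <- max(1L, floor(cx[k] - r)):min(npx, ceiling(cx[k] + r))
        dy <- ys - cy[k]; dx <- xs - cx[k]
        disc <- outer(dy^2, dx^2, "+") <= r^2
        if (any(disc)) {
          sub <- pot_field[ys, xs, drop = FALSE]
          pot_field[ys, xs] <- ifelse(disc, pmax(sub, base_pot[k]), sub)
        }
      }
      # the decay constant is a property of the local membrane patch, so
      # the envelope is applied per pixel with the pixel's own tau
      tau_c <- tau_field[cbind(pmin(pmax(round(cy), 1), npx),
                               pmin(pmax(round(cx), 1), npx))]
      env_c <- sh_envelope(t_frame_min[f], spec$t_acid_min,
                              spec$rise_min, tau_c, norm)
      dom_list[[f]] <- data.frame(
        frame = f, time_min = t_frame_min[f], cx = cx, cy = cy,
        radius_px = rad_px, base_potential_V = base_pot,
        realized_potential_V = base_pot * env_c, tau_min = tau_c)
    }
    env_px <- matrix(sh_envelope(t_frame_min[f], spec$t_acid_min,
                                    spec$rise_min, tau_field, norm), npx)
    frames[, , f] <- spec$baseline_counts +
      intensity_from_potential(pot_field * env_px, spec$cal)
  }
  # noise applied last: shot noise on expected counts, then read noise
  noisy <- array(stats::rpois(length(frames), frames), dim = dim(frames))
  if (spec$read_noise_sd > 0) {
    noisy <- noisy + array(stats::rnorm(length(frames), 0,
                                        spec$read_noise_sd),
                           dim = dim(frames))
  }
  truth <- list(
    domains = do.call(rbind, dom_list[!vapply(dom_list, is.null, logical(1))]),
    tau_field = tau_field, tau_tiles = tau_tiles, tile_px = tile_px,
    envelope = list(t_acid_min = spec$t_acid_min, rise_min = spec$rise_min,
                    norm = norm),
    frame_windows = frame_windows, window_times_min = window_times_min,
    spec = spec)
  list(stack = sh_stack(noisy, times_s = t_frame_min * 60,
                        pixel_size_um = spec$pixel_um,
                        metadata = list(t_acid_s = spec$t_acid_min * 60,
                                        frame_windows = frame_windows)),
       truth = truth)
}

#' Generate a synthetic I-V sweep
#'
#' `I = G (V - V_rev) + N(0, noise_sigma)`; deterministic under the seed.
#'
#' @param G conductance, S
#' @param V_rev reversal potential, V
#' @param n_points number of voltage points (>= 2), evenly spaced over
#'   `v_range`
#' @param noise_sigma current noise SD, A
#' @param seed RNG seed
#' @param v_range swept voltage range, V
#' @param label record label
#' @return list with `iv` (an [iv_record()]) and `truth`
#'   (G, V_rev, noise_sigma, seed)
#' @export
gen_iv <- function(G, V_rev = 0, n_points = 11, noise_sigma = 0,
                   seed = 1L, v_range = c(-0.06, 0.06), label = "synthetic") {
  stopifnot(n_points >= 2, noise_sigma >= 0)
  set.seed(seed)
  v <- seq(v_range[1], v_range[2], length.out = n_points)
  i <- G * (v - V_rev)
  if (noise_sigma > 0) i <- i + stats::rnorm(n_points, 0, noise_sigma)
  list(iv = iv_record(v, i, label = label),
       truth = list(G = G, V_rev = V_rev, noise_sigma = noise_sigma,
                    seed = seed))
}

#' Generate synthetic defect free-energy and flux profiles
#'
#' Smooth monotone-rising free energy with a steep rise past
#' `barrier_xi` (quartic in the rescaled coordinate) and a sigmoidal flux
#' turning on near xi = 0.74, emulating chain-coordinate PMF and flux
#' curves. An optional `ddG_offset` raises the profile by a fixed amount
#' through a smooth switch that is ~1 everywhere the flux is nonzero while
#' preserving `dG(0.1) = 0`, so a pair of profiles differing only in
#' `ddG_offset` has an integrated-permeability ratio of
#' `exp(beta * ddG_offset)` to high accuracy.
#'
#' @param barrier_height free energy scale, kJ/mol (value at xi = 1 before
#'   offset)
#' @param barrier_xi coordinate past which the rise steepens (shapes the
#'   quartic; default 0.85)
#' @param flux_scale flux plateau, ions/s
#' @param ddG_offset additional offset, kJ/mol (see above)
#' @param flux_onset_xi sigmoid center of the flux turn-on
#' @param noise_sigma optional relative Gaussian noise on both curves
#' @param seed RNG seed (used only when `noise_sigma > 0`)
#' @param xi chain-coordinate grid
#' @param label profile label
#' @return list with `profiles` (a [defect_profiles()]) and `truth`
#' @export
gen_defect_profiles <- function(barrier_height = 60, barrier_xi = 0.85,
                                flux_scale = 1e7, ddG_offset = 0,
                                flux_onset_xi = 0.74, noise_sigma = 0,
                                seed = 1L, xi = seq(0.1, 1, by = 0.02),
                                label = "synthetic") {
  stopifnot(barrier_height > 0, flux_scale >= 0, noise_sigma >= 0)
  # quartic rise calibrated so dG(barrier_xi) = barrier_height / 2
  g <- ((xi - 0.1) / (barrier_xi - 0.1))^4 / 2
  dG <- barrier_height * g
  sw <- stats::plogis((xi - 0.35) / 0.04)
  sw <- (sw - sw[1]) / (stats::plogis((1 - 0.35) / 0.04) - sw[1])
  dG <- dG + ddG_offset * sw
  # no water-wire connectivity below xi ~ 0.62: flux strictly zero there,
  # then a sigmoidal turn-on centered at the needle-formation coordinate
  flux <- flux_scale * stats::plogis((xi - flux_onset_xi) / 0.03)
  flux[xi < 0.62] <- 0
  if (noise_sigma > 0) {
    set.seed(seed)
    dG <- dG * (1 + stats::rnorm(length(xi), 0, noise_sigma))
    flux <- pmax(flux * (1 + stats::rnorm(length(xi), 0, noise_sigma)), 0)
    dG <- dG - dG[1]
  }
  list(profiles = defect_profiles(xi, dG - dG[1], flux, label = label),
       truth = list(barrier_height = barrier_height, barrier_xi = barrier_xi,
                    flux_scale = flux_scale, ddG_offset = ddG_offset,
                    flux_onset_xi = flux_onset_xi,
                    noise_sigma = noise_sigma, seed = seed))
}
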