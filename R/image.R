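#' SH image stack container
#'
#' @param frames numeric array `[ny, nx, nframe]` of detected counts
#' @param times_s frame acquisition times in seconds (length nframe)
#' @param pixel_size_um pixel size in micrometers
#' @param metadata optional named list (e.g. `t_acid_s`, the HCl-addition
#'   timestamp)
#' @return object of class `sh_stack`
#' @export
sh_stack <- function(frames, times_s, pixel_size_um, metadata = list()) {
  stopifnot(is.array(frames), length(dim(frames)) == 3,
            length(times_s) == dim(frames)[3], pixel_size_um > 0)
  structure(list(frames = frames, times_s = times_s,
                 pixel_size_um = pixel_size_um, metadata = metadata),
            class = "sh_stack")
}

#' @export
print.sh_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "SH stack: %d x %d px (%.2g um/px), %d frames, t = %.3g..%.3g s\n",
    d[1], d[2], x$pixel_size_um, d[3], min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' Robust background statistics of a frame
#'
#' Median and MAD-based sigma; valid when signal domains are sparse.
#'
#' @param frame numeric matrix
#' @return list with `median` and `sigma`
#' @export
background_stats <- function(frame) {
  list(median = stats::median(frame),
       sigma = stats::mad(frame))
}

#' Segment bright SH domains in one frame
#'
#' Thresholds at `background median + k_sigma * robust sigma`, labels
#' 4-connected components (EBImage), drops components smaller than
#' `min_area_px` pixels, and attaches per-domain mean intensity and (when a
#' calibration is given) mean potential computed from background-subtracted
#' intensity.
#'
#' @param frame numeric matrix of counts
#' @param pixel_size_um pixel size, um
#' @param k_sigma threshold in robust sigmas above background (default 3)
#' @param min_area_px minimum component area in pixels (default 4)
#' @param cal optional [sh_calibration()] for potential conversion
#' @param background optional fixed background level; estimated from the
#'   frame median when `NULL`
#' @param frame_index frame index recorded in the catalog
#' @return a `data.frame` (class `domain_catalog`) with one row per domain:
#'   `frame`, `x`, `y` (centroid, px), `area_px`, `area_um2`,
#'   `mean_intensity` (raw counts), `mean_potential_V` (NA without
#'   calibration), and a `pixels` list-column of linear pixel indices
#' @export
segment_domains <- function(frame, pixel_size_um = 1, k_sigma = 3,
                            min_area_px = 4, cal = NULL, background = NULL,
                            frame_index = 1L) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  bg <- background_stats(frame)
  bg_level <- if (is.null(background)) bg$median else background
  thr <- bg$median + k_sigma * bg$sigma
  mask <- frame > thr
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      area_px = integer(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0),
                      mean_potential_V = numeric(0))
  empty$pixels <- list()
  class(empty) <- c("domain_catalog", "data.frame")
  if (!any(mask)) return(empty)
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(EBImage::imageData(labels))
  idx <- which(lab > 0L)
  lab <- lab[idx]
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area_px)
  if (!length(keep)) return(empty)
  sel <- lab %in% keep
  idx <- idx[sel]; lab <- lab[sel]
  ny <- nrow(frame)
  rows <- ((idx - 1L) %% ny) + 1L
  cols <- ((idx - 1L) %/% ny) + 1L
  vals <- frame[idx]
  o <- order(lab)
  idx <- idx[o]; lab <- lab[o]; rows <- rows[o]; cols <- cols[o]; vals <- vals[o]
  grp <- factor(lab)
  area_px <- as.integer(table(grp))
  mean_int <- as.numeric(tapply(vals, grp, mean))
  cx <- as.numeric(tapply(cols, grp, mean))
  cy <- as.numeric(tapply(rows, grp, mean))
  mean_pot <- rep(NA_real_, length(area_px))
  if (!is.null(cal)) {
    pot <- potential_from_intensity(pmax(vals - bg_level, 0), cal)
    mean_pot <- as.numeric(tapply(pot, grp, mean))
  }
  out <- data.frame(frame = frame_index, x = cx, y = cy,
                    area_px = area_px,
                    area_um2 = area_px * pixel_size_um^2,
                    mean_intensity = mean_int,
                    mean_potential_V = mean_pot)
  out$pixels <- unname(split(idx, grp))
  class(out) <- c("domain_catalog", "data.frame")
  out
}

#' Segment every frame of a stack
#'
#' @param stack an [sh_stack()]
#' @param frames which frame indices to segment (default all)
#' @inheritParams segment_domains
#' @return a combined `domain_catalog` data.frame
#' @export
segment_stack <- function(stack, frames = seq_len(dim(stack$frames)[3]),
                          k_sigma = 3, min_area_px = 4, cal = NULL,
                          background = NULL) {
  stopifnot(inherits(stack, "sh_stack"))
  cats <- lapply(frames, function(f) {
    segment_domains(stack$frames[, , f], pixel_size_um = stack$pixel_size_um,
                    k_sigma = k_sigma, min_area_px = min_area_px, cal = cal,
                    background = background, frame_index = f)
  })
  out <- do.call(rbind, cats)
  class(out) <- c("domain_catalog", "data.frame")
  out
}

#' Fit a Gaussian to a sample by histogram least squares
#'
#' Bins the values and least-squares fits `a * exp(-(x - mu)^2 / (2 sigma^2))`
#' to the bin counts (the convention used for occurrence histograms). Falls
#' back to sample moments, flagged unreliable, when the nonlinear fit
#' degenerates.
#'
#' @param values numeric sample
#' @param bins number of bins or a vector of break points
#' @param min_n fits from fewer than `min_n` values are flagged unreliable
#' @return list with `mu`, `sigma`, `amplitude`, `bin_centers`, `counts`,
#'   `reliable`
#' @export
fit_gaussian_histogram <- function(values, bins = 25, min_n = 5) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) stop("no finite values to histogram")
  reliable <- n >= min_n && stats::sd(values) > 0
  h <- graphics::hist(values, breaks = bins, plot = FALSE)
  centers <- h$mids
  counts <- h$counts
  # robust initialization and bounds: the mode must lie within the data
  # range and the width cannot exceed it, so a skewed tail cannot drag the
  # fit off the histogram body
  mu0 <- stats::median(values)
  s0 <- max(stats::mad(values), diff(range(centers)) / 20, 1e-12)
  mu <- mu0; sigma <- s0; a <- max(counts)
  if (reliable) {
    rng <- range(values)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        counts ~ a * exp(-(centers - mu)^2 / (2 * s^2)),
        start = list(a = max(counts), mu = mu0, s = s0),
        lower = c(0, rng[1], 1e-12),
        upper = c(Inf, rng[2], diff(rng) + 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      reliable <- FALSE
    } else {
      cf <- stats::coef(fit)
      a <- unname(cf["a"]); mu <- unname(cf["mu"]); sigma <- abs(unname(cf["s"]))
    }
  }
  list(mu = mu, sigma = sigma, amplitude = a,
       bin_centers = centers, counts = counts, reliable = reliable)
}

#' Occurrence histogram of per-domain potentials with Gaussian fit
#'
#' Pools per-domain mean potentials over the frames of an observation window
#' (20 one-second frames in the standard acquisition) and fits a Gaussian to
#' the occurrence counts, returning its mean and standard deviation.
#'
#' @param catalog a `domain_catalog` (from [segment_stack()]) or a numeric
#'   vector of per-domain potentials (V)
#' @param bins histogram bins (count or breaks)
#' @return object of class `domain_histogram` with `mu`, `sigma`,
#'   `bin_centers`, `counts`, `n_domains`, `reliable`
#' @export
domain_occurrence_histogram <- function(catalog, bins = 25) {
  pot <- if (is.data.frame(catalog)) catalog$mean_potential_V else catalog
  pot <- pot[is.finite(pot)]
  if (!length(pot)) stop("no domains with finite potentials")
  g <- fit_gaussian_histogram(pot, bins = bins, min_n = 5)
  structure(list(mu = g$mu, sigma = g$sigma,
                 bin_centers = g$bin_centers, counts = g$counts,
                 n_domains = length(pot), reliable = g$reliable),
            class = "domain_histogram")
}

#' @export
print.domain_histogram <- function(x, ...) {
  cat(sprintf(
    "Domain potential histogram: n = %d, mu = %.4g V, sigma = %.4g V%s\n",
    x$n_domains, x$mu, x$sigma,
    if (x$reliable) "" else "  [fit unreliable]"))
  invisible(x)
}

#' Windowed mean domain potential series
#'
#' Area-weighted mean of per-domain potentials in each observation window.
#' Windows with no detected domains are recorded as missing (NA), not zero.
#'
#' @param catalog a `domain_catalog` covering all frames
#' @param frame_windows list of integer vectors: the frame indices of each
#'   window
#' @param window_times_min time stamp (minutes) of each window
#' @return data.frame (class `potential_series`) with `time_min`,
#'   `mean_potential_V`, `n_domains`
#' @export
mean_domain_potential_series <- function(catalog, frame_windows,
                                         window_times_min) {
  stopifnot(is.data.frame(catalog), length(frame_windows) >= 2,
            length(frame_windows) == length(window_times_min))
  if (!nrow(catalog)) stop("empty domain catalog")
  rows <- lapply(seq_along(frame_windows), function(w) {
    sub <- catalog[catalog$frame %in% frame_windows[[w]] &
                     is.finite(catalog$mean_potential_V), , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(time_min = window_times_min[w],
                        mean_potential_V = NA_real_, n_domains = 0L))
    }
    data.frame(
      time_min = window_times_min[w],
      mean_potential_V = sum(sub$mean_potential_V * sub$area_um2) /
        sum(sub$area_um2),
      n_domains = nrow(sub))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("potential_series", "data.frame")
  out
}

#' Fit an exponential decay to a time series
#'
#' Least-squares fit of `A * exp(-(t - t_start)/tau) + baseline` to the
#' decaying part of a rise-then-decay series. When `t_start` is `NULL` it is
#' auto-detected as the post-smoothing maximum of the series (the decay
#' starts at the peak). Non-decaying or flat series are fitted but flagged.
#'
#' @param time_min sample times, minutes
#' @param values series values (potential, counts, ...); NAs dropped
#' @param t_start fit start time (minutes), or `NULL` to auto-detect
#' @param tau_max upper bound for tau (minutes); fits at the bound are
#'   flagged
#' @param weighting `"relative"` (default) reweights a second fitting pass
#'   by the inverse squared fitted value, appropriate when the noise is
#'   multiplicative (as it is for domain-count fluctuations in SH window
#'   series); `"uniform"` is plain unweighted least squares
#' @param baseline fix the baseline at this value instead of fitting it;
#'   use 0 for background-subtracted signals (removes the tau/baseline
#'   degeneracy that destabilizes slow decays)
#' @return object of class `decay_fit`: `amplitude`, `tau_min`, `baseline`,
#'   `t_start`, `rmse`, `flagged`, `flag_reason`
#' @export
#' @examples
#' t <- seq(0, 200, by = 4)
#' y <- 0.1 * exp(-t / 67) + 0.01
#' fit_exponential_decay(t, y, t_start = 0)$tau_min  # 67
fit_exponential_decay <- function(time_min, values, t_start = NULL,
                                  tau_max = 1e4,
                                  weighting = c("relative", "uniform"),
                                  baseline = NULL) {
  weighting <- match.arg(weighting)
  ok <- is.finite(time_min) & is.finite(values)
  t <- time_min[ok]; y <- values[ok]
  if (is.null(t_start)) {
    k <- min(3L, length(y))
    sm <- stats::filter(y, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- y[is.na(sm)]
    t_start <- t[which.max(sm)]
  }
  sel <- t >= t_start
  if (sum(sel) < 4) stop("need at least 4 points at or after t_start")
  td <- t[sel] - t_start
  yd <- y[sel]
  b0 <- if (is.null(baseline)) min(yd) else baseline
  A0 <- max(yd) - b0
  # log-linear initial tau from the upper part of the decay
  pos <- yd - b0 > 0.05 * max(A0, 1e-300)
  tau0 <- if (sum(pos) >= 2 && A0 > 0) {
    sl <- stats::coef(stats::lm(log(yd[pos] - b0 + 0.05 * A0) ~ td[pos]))[2]
    if (is.finite(sl) && sl < 0) min(-1 / sl, tau_max) else diff(range(td)) / 2
  } else diff(range(td)) / 2
  tau0 <- max(tau0, 1e-3)
  do_fit <- function(start, weights = NULL) {
    args <- if (is.null(baseline)) {
      list(yd ~ A * exp(-td / tau) + b, start = start,
           lower = c(-Inf, 1e-6, -Inf), upper = c(Inf, tau_max, Inf),
           control = minpack.lm::nls.lm.control(maxiter = 300))
    } else {
      list(yd ~ A * exp(-td / tau) + baseline,
           start = start[c("A", "tau")],
           lower = c(-Inf, 1e-6), upper = c(Inf, tau_max),
           control = minpack.lm::nls.lm.control(maxiter = 300))
    }
    if (!is.null(weights)) args$weights <- weights
    tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
  }
  fit <- do_fit(list(A = max(A0, 1e-12), tau = tau0, b = b0))
  if (!is.null(fit) && weighting == "relative") {
    fv <- stats::fitted(fit)
    w <- 1 / pmax(abs(fv), 0.05 * max(abs(fv), 1e-300))^2
    cf0 <- as.list(stats::coef(fit))
    refit <- do_fit(list(A = max(cf0$A, 1e-12), tau = cf0$tau,
                         b = cf0$b %||% b0), weights = w)
    if (!is.null(refit)) fit <- refit
  }
  if (is.null(fit)) {
    return(structure(list(amplitude = 0, tau_min = NA_real_, baseline = b0,
                          t_start = t_start, rmse = stats::sd(yd),
                          flagged = TRUE, flag_reason = "fit failed"),
                     class = "decay_fit"))
  }
  cf <- stats::coef(fit)
  A <- unname(cf["A"]); tau <- unname(cf["tau"])
  b <- if (is.null(baseline)) unname(cf["b"]) else baseline
  rmse <- sqrt(mean(stats::resid(fit)^2))
  span <- max(abs(yd) , 1e-300)
  flagged <- FALSE; reason <- ""
  if (abs(A) <= 1e-3 * span) {
    flagged <- TRUE; reason <- "amplitude ~ 0 (flat series)"
  } else if (A < 0) {
    flagged <- TRUE; reason <- "negative amplitude (non-decaying series)"
  } else if (tau >= 0.999 * tau_max) {
    flagged <- TRUE; reason <- "tau at upper bound (non-decaying series)"
  }
  structure(list(amplitude = A, tau_min = tau, baseline = b,
                 t_start = t_start, rmse = rmse,
                 flagged = flagged, flag_reason = reason),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential decay fit: tau = %.4g min, A = %.4g, baseline = %.4g (t_start = %.3g min, rmse = %.3g)%s\n",
    x$tau_min, x$amplitude, x$baseline, x$t_start, x$rmse,
    if (x$flagged) paste0("  [", x$flag_reason, "]") else ""))
  invisible(x)
}

#' Window-mean signal cube from a frame stack
#'
#' Averages the counts of the frames within each observation window (the
#' 20-frame averages of the standard acquisition), then optionally
#' background-subtracts and converts the averaged image to potential
#' magnitude. Averaging before the square-root conversion keeps the shot
#' noise zero-mean; converting individual noisy frames first would rectify
#' the noise into a spurious baseline.
#'
#' @param stack an [sh_stack()]
#' @param frame_windows list of frame-index vectors
#' @param mode `"counts"` returns raw window means; `"intensity_excess"`
#'   subtracts the background (zero-mean noise is preserved, no clamping —
#'   the right signal for decay fitting); `"potential"` additionally
#'   applies the square-root potential conversion of `cal` to the clamped
#'   excess (for maps and display; the clamp rectifies noise into a small
#'   constant floor)
#' @param cal an [sh_calibration()], required for `mode = "potential"`
#' @param background background counts; when `NULL`, estimated per window
#'   as the median over the window's raw frames (domains are sparse within
#'   a single frame, so the per-frame median is uncontaminated, whereas
#'   most pixels of the window-averaged image carry some domain signal)
#' @return array `[ny, nx, n_windows]`
#' @export
window_mean_cube <- function(stack, frame_windows,
                             mode = c("counts", "intensity_excess",
                                      "potential"),
                             cal = NULL, background = NULL) {
  stopifnot(inherits(stack, "sh_stack"))
  mode <- match.arg(mode)
  if (mode == "potential" && is.null(cal)) {
    stop("mode = 'potential' needs a calibration")
  }
  d <- dim(stack$frames)
  out <- array(0, dim = c(d[1], d[2], length(frame_windows)))
  for (w in seq_along(frame_windows)) {
    fr <- stack$frames[, , frame_windows[[w]], drop = FALSE]
    avg <- apply(fr, c(1, 2), mean)
    if (mode != "counts") {
      bg <- if (is.null(background)) stats::median(fr) else background
      avg <- avg - bg
      if (mode == "potential") {
        avg <- matrix(potential_from_intensity(pmax(avg, 0), cal),
                      nrow = d[1])
      }
    }
    out[, , w] <- avg
  }
  out
}

#' Map exponential decay constants over a grid of ROIs
#'
#' Tiles the field of view into non-overlapping square ROIs, averages the
#' signal within each ROI for every observation window, and fits each ROI
#' series with [fit_exponential_decay()]. ROIs whose fit fails or is flagged
#' are recorded as missing.
#'
#' @param cube window-mean signal array `[ny, nx, n_windows]` (see
#'   [window_mean_cube()])
#' @param window_times_min window time stamps, minutes
#' @param roi_size_px ROI edge length in pixels (e.g. 9 px = 4.5 um at
#'   0.5 um/px); ROIs are cropped to the largest complete grid
#' @param t_start decay-fit start time (minutes), `NULL` to auto-detect per
#'   ROI
#' @param tau_scale factor applied to the fitted decay constant before
#'   reporting: 1 when the cube is a potential-like signal, 2 when it is SH
#'   intensity (the quadratic SH response makes intensity decay twice as
#'   fast as the potential)
#' @param baseline passed to [fit_exponential_decay()]; use 0 when the cube
#'   is background-subtracted intensity
#' @param calibration_K tau-to-flux anchor constant (see [tau_to_flux()])
#' @return object of class `tau_map`: matrices `tau` and `flux`
#'   (ions/s), `amplitude`, plus grid metadata
#' @export
roi_tau_map <- function(cube, window_times_min, roi_size_px,
                        t_start = NULL, tau_scale = 1, baseline = NULL,
                        calibration_K = tau_flux_anchor()) {
  stopifnot(is.array(cube), length(dim(cube)) == 3,
            dim(cube)[3] == length(window_times_min), roi_size_px >= 1)
  d <- dim(cube)
  nry <- d[1] %/% roi_size_px
  nrx <- d[2] %/% roi_size_px
  if (nry < 1 || nrx < 1) stop("ROI larger than the field of view")
  tau <- matrix(NA_real_, nry, nrx)
  amp <- matrix(NA_real_, nry, nrx)
  for (iy in seq_len(nry)) {
    ys <- ((iy - 1) * roi_size_px + 1):(iy * roi_size_px)
    for (ix in seq_len(nrx)) {
      xs <- ((ix - 1) * roi_size_px + 1):(ix * roi_size_px)
      series <- apply(cube[ys, xs, , drop = FALSE], 3, mean)
      fit <- tryCatch(
        fit_exponential_decay(window_times_min, series, t_start = t_start,
                              baseline = baseline),
        error = function(e) NULL)
      if (!is.null(fit) && !fit$flagged) {
        tau[iy, ix] <- tau_scale * fit$tau_min
        amp[iy, ix] <- fit$amplitude
      }
    }
  }
  structure(list(tau = tau, flux = calibration_K / tau, amplitude = amp,
                 roi_size_px = roi_size_px, n_fitted = sum(is.finite(tau))),
            class = "tau_map")
}

#' @export
print.tau_map <- function(x, ...) {
  cat(sprintf(
    "tau map: %d x %d ROIs (%d fitted), tau = %.3g +/- %.3g min\n",
    nrow(x$tau), ncol(x$tau), x$n_fitted,
    mean(x$tau, na.rm = TRUE), stats::sd(x$tau, na.rm = TRUE)))
  invisible(x)
}

#' Anchor constant for the tau-to-flux conversion
#'
#' The decay constant of the whole-membrane potential series and the
#' membrane-wide translocation flux are inversely proportional; one anchor
#' pair fixes the constant `K = F_ref * tau_ref`. The default anchor is the
#' unsaturated (DOPC:DOPS) membrane: tau = 67 min maps to 7.5e6 ions/s.
#'
#' @param tau_ref_min anchor decay constant, minutes
#' @param flux_ref anchor flux, ions/s
#' @return K in ions * min / s
#' @export
tau_flux_anchor <- function(tau_ref_min = 67, flux_ref = 7.5e6) {
  stopifnot(tau_ref_min > 0, flux_ref > 0)
  tau_ref_min * flux_ref
}

#' Convert a decay constant to a translocation flux
#'
#' `flux = K / tau` with the anchor constant K from [tau_flux_anchor()];
#' `flux * tau = K` for every tau.
#'
#' @param tau_min decay constant(s), minutes (> 0)
#' @param calibration_K anchor constant, ions * min / s
#' @return flux in ions/s
#' @export
#' @examples
#' tau_to_flux(67)  # 7.5e6
#' tau_to_flux(42)  # ~1.2e7
tau_to_flux <- function(tau_min, calibration_K = tau_flux_anchor()) {
  stopifnot(all(tau_min > 0, na.rm = TRUE), calibration_K > 0)
  calibration_K / tau_min
}
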