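make_blob_frame <- function(n = 90, blobs, amp = 300, bg = 20, r = 3,
                            seed = 1) {
  set.seed(seed)
  frame <- matrix(rpois(n * n, bg), n, n)
  for (k in seq_len(nrow(blobs))) {
    ys <- pmax(1, round(blobs$y[k] - r)):pmin(n, round(blobs$y[k] + r))
    xs <- pmax(1, round(blobs$x[k] - r)):pmin(n, round(blobs$x[k] + r))
    disc <- outer((ys - blobs$y[k])^2, (xs - blobs$x[k])^2, "+") <= r^2
    frame[ys, xs] <- frame[ys, xs] + disc * amp
  }
  frame
}

test_that("segmentation finds isolated blobs and rejects noise", {
  # pure-noise frame: no domains above min_area
  set.seed(3)
  noise <- matrix(rpois(90 * 90, 20), 90, 90)
  expect_equal(nrow(segment_domains(noise)), 0)

  # 12 well-separated blobs: all recovered with centroids within 1 px
  centers <- expand.grid(x = c(15, 35, 55, 75), y = c(15, 45, 75))
  frame <- make_blob_frame(90, centers)
  cat0 <- segment_domains(frame, pixel_size_um = 0.5)
  expect_equal(nrow(cat0), 12)
  for (k in seq_len(12)) {
    d <- sqrt((cat0$x - centers$x[k])^2 + (cat0$y - centers$y[k])^2)
    expect_lt(min(d), 1)
  }
  # area attached in physical units
  expect_equal(cat0$area_um2, cat0$area_px * 0.25, tolerance = 1e-12)
})

test_that("segmentation drops blobs below the minimum area", {
  frame <- matrix(20, 90, 90)
  frame[10:15, 10:15] <- 400    # 36 px blob
  frame[50, 50] <- 400          # single pixel
  frame <- frame + matrix(rnorm(8100, 0, 2), 90, 90)
  cat0 <- segment_domains(frame, min_area_px = 4)
  expect_equal(nrow(cat0), 1)
  expect_equal(cat0$area_px, 36)
})

test_that("segmentation is idempotent and threshold is intensity-relative", {
  centers <- data.frame(x = c(20, 60), y = c(30, 70))
  frame <- make_blob_frame(90, centers, amp = 300, bg = 100, seed = 9)
  a <- segment_domains(frame)
  b <- segment_domains(frame)
  expect_identical(a[names(a) != "pixels"], b[names(b) != "pixels"])
  # rescaling intensities leaves the segmentation unchanged (relative
  # threshold): same components in the same order
  c2 <- segment_domains(frame * 3.7)
  expect_equal(nrow(c2), nrow(a))
  expect_equal(c2$area_px, a$area_px)
  expect_equal(c2$x, a$x)
})

test_that("occurrence histogram recovers a Gaussian potential sample", {
  set.seed(11)
  pots <- rnorm(500, 0.12, 0.05)
  h <- domain_occurrence_histogram(pots)
  expect_true(h$reliable)
  expect_equal(h$mu, 0.12, tolerance = 0.007 / 0.12)
  expect_equal(h$sigma, 0.05, tolerance = 0.007 / 0.05)
  # translation equivariance
  h2 <- domain_occurrence_histogram(pots + 0.05)
  expect_equal(h2$mu, h$mu + 0.05, tolerance = 0.003 / h$mu)
  # degenerate sample is flagged
  h3 <- domain_occurrence_histogram(rep(0.2, 50))
  expect_false(h3$reliable)
  h4 <- domain_occurrence_histogram(c(0.1, 0.12, 0.14))
  expect_false(h4$reliable)
})

test_that("windowed mean domain potential series peaks with the envelope", {
  res <- gen_sh_stack(sh_stack_spec(seed = 13, n_windows = 20,
                                    window_spacing_min = 5))
  truth <- res$truth
  cat0 <- segment_stack(res$stack, cal = res$truth$spec$cal)
  ser <- mean_domain_potential_series(cat0, truth$frame_windows,
                                      truth$window_times_min)
  expect_s3_class(ser, "potential_series")
  # the series peak lies at the envelope peak window (rise ~2 min after
  # acid at t = 10 min, windows every 5 min) within one window
  tpk_true <- 10 + 2 * log(1 + truth$spec$tau_mu_min / 2)
  tpk_obs <- ser$time_min[which.max(ser$mean_potential_V)]
  expect_lt(abs(tpk_obs - tpk_true), 5 + 1e-9)
  expect_error(mean_domain_potential_series(cat0[0, ],
                                            truth$frame_windows,
                                            truth$window_times_min),
               "empty")
})

test_that("exponential decay fit recovers exact decay constants", {
  t <- seq(0, 400, by = 4)
  for (tau in c(67, 442)) {
    y <- 0.08 * exp(-t / tau) + 0.005
    fit <- fit_exponential_decay(t, y, t_start = 0)
    expect_false(fit$flagged)
    expect_equal(fit$tau_min, tau, tolerance = 1e-3)
    expect_equal(fit$baseline, 0.005, tolerance = 1e-3)
  }
  # constant series: near-zero amplitude, flagged
  flat <- fit_exponential_decay(t, rep(0.02, length(t)), t_start = 0)
  expect_true(flat$flagged)
  # rising series: flagged as non-decaying
  rising <- fit_exponential_decay(t, 0.01 + 1e-4 * t, t_start = 0,
                                  tau_max = 1e3)
  expect_true(rising$flagged)
  expect_error(fit_exponential_decay(c(1, 2, 3), c(3, 2, 1), t_start = 1))
})

test_that("decay start is auto-detected at the series peak", {
  t <- seq(0, 200, by = 2.5)
  y <- (1 - exp(-pmax(t - 10, 0) / 2)) * exp(-pmax(t - 10, 0) / 50)
  fit <- fit_exponential_decay(t, y)
  tpk <- 10 + 2 * log(1 + 50 / 2)
  expect_lt(abs(fit$t_start - tpk), 5)
  expect_equal(fit$tau_min, 50, tolerance = 0.10)
})

test_that("ROI tau map recovers a clean tau field within stated bounds", {
  set.seed(21)
  n <- 10
  taus <- matrix(0, n, n)
  for (i in seq_len(n * n)) {
    repeat {
      v <- rnorm(1, 42, 24)
      if (v > 5) break
    }
    taus[i] <- v
  }
  t <- seq(0, 150, by = 2.5)
  cube <- array(0, dim = c(n, n, length(t)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cube[i, j, ] <- 0.1 * exp(-t / taus[i, j]) *
      (1 + rnorm(length(t), 0, 0.02))
  }
  tm <- roi_tau_map(cube, t, 1, t_start = 0)
  expect_gte(tm$n_fitted, 99)
  # recovered histogram Gaussian against the realized field's own fit
  # (the N(42, 24) draw carries sampling error at 100 tiles)
  g <- fit_gaussian_histogram(as.vector(tm$tau))
  gt <- fit_gaussian_histogram(as.vector(taus))
  expect_lt(abs(g$mu - gt$mu), 3)
  expect_lt(abs(g$sigma - gt$sigma), 4)
  # flux map is elementwise K / tau
  expect_equal(tm$flux, tau_flux_anchor() / tm$tau, tolerance = 1e-12)
})

test_that("a single whole-field ROI equals the whole-field fit", {
  res <- gen_sh_stack(sh_stack_spec(seed = 17))
  truth <- res$truth
  cube <- window_mean_cube(res$stack, truth$frame_windows,
                           mode = "intensity_excess")
  wt <- truth$window_times_min
  field <- apply(cube, 3, mean)
  wf <- fit_exponential_decay(wt, field)
  tm <- roi_tau_map(cube, wt, dim(cube)[1], t_start = wf$t_start,
                    tau_scale = 2)
  expect_equal(dim(tm$tau), c(1L, 1L))
  expect_equal(tm$tau[1, 1], 2 * wf$tau_min, tolerance = 1e-6)
  # ROI larger than the field errors
  expect_error(roi_tau_map(cube, wt, dim(cube)[1] + 1), "larger")
})

test_that("tau-to-flux conversion is anchored and inverse-proportional", {
  expect_equal(tau_to_flux(67), 7.5e6)
  expect_equal(signif(tau_to_flux(42), 2), 1.2e7)
  taus <- c(10, 42, 67, 200)
  expect_equal(tau_to_flux(taus) * taus, rep(tau_flux_anchor(), 4),
               tolerance = 1e-12)
})
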