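## minimal roi_series constructor for ratio-level tests
series_stub <- function(cell, is, cis, dt = 5) {
  structure(list(times_min = (seq_along(cell) - 1) * dt, cell_fi = cell,
                 is_fi = is, cis_fi = cis,
                 flagged = rep(FALSE, length(cell)), masks = NULL),
            class = "roi_series")
}

test_that("uniform intensities give unit ratios; doubling doubles", {
  k <- actin_ratio_series(series_stub(rep(2, 4), rep(2, 4), rep(2, 4)))
  expect_equal(k$ratio_is_cell, rep(1, 4))
  expect_equal(k$ratio_cis_is, rep(1, 4))
  k2 <- actin_ratio_series(series_stub(rep(1, 3), rep(2, 3), rep(2, 3)))
  expect_equal(k2$ratio_is_cell, rep(2, 3))
})

test_that("zero-denominator frames are excluded with a warning", {
  expect_warning(
    k <- actin_ratio_series(series_stub(c(1, 0, 1), c(1, 1, 1), c(1, 1, 1))),
    class = "zero_denominator")
  expect_true(is.na(k$ratio_is_cell[2]))
})

test_that("reorganization interval matches the exhaustive-scan oracle", {
  ## oracle: scan all contiguous runs above 1 + delta, take the longest
  oracle <- function(r, dt, delta = 0.05) {
    above <- r > 1 + delta
    best <- 0
    for (i in seq_along(r)) for (j in i:length(r))
      if (all(above[i:j]) && (j - i + 1) > best) best <- j - i + 1
    best * dt
  }
  r <- c(0.9, 1.2, 1.5, 1.3, 0.95)
  k <- actin_ratio_series(series_stub(rep(1, 5), r, r))
  out <- reorganization_interval(k)
  expect_equal(out$duration, 15)
  expect_equal(out$duration, oracle(r, 5))
  expect_equal(out$max_ratio, 1.5)
  expect_equal(out$peak_time, 10)

  set.seed(21)
  for (rep in 1:10) {
    r <- runif(12, 0.8, 1.6)
    k <- actin_ratio_series(series_stub(rep(1, 12), r, r, dt = 3))
    expect_equal(reorganization_interval(k)$duration, oracle(r, 3))
  }

  const <- actin_ratio_series(series_stub(rep(1, 5), rep(1, 5), rep(1, 5)))
  expect_equal(reorganization_interval(const)$duration, 0)
  low <- actin_ratio_series(series_stub(rep(1, 4), c(0.7, 0.9, 0.8, 0.6),
                                        rep(1, 4)))
  out_low <- reorganization_interval(low)
  expect_equal(out_low$duration, 0)
  expect_equal(out_low$max_ratio, 0.9)
})

test_that("depletion interval finds the longest sub-unity run", {
  r <- c(1.0, 0.7, 0.6, 0.9, 1.05)
  k <- actin_ratio_series(series_stub(rep(1, 5), rep(1, 5), r))
  out <- depletion_interval(k)
  expect_true(out$depletion_present)
  expect_equal(out$depletion_duration, 15)
  const <- actin_ratio_series(series_stub(rep(1, 4), rep(1, 4), rep(1, 4)))
  expect_false(depletion_interval(const)$depletion_present)
})

test_that("durations are invariant to uniform intensity scaling", {
  set.seed(31)
  r <- runif(10, 0.7, 1.8)
  cis <- runif(10, 0.5, 1.3)
  a <- actin_ratio_series(series_stub(rep(2, 10), 2 * r, 2 * r * cis))
  b <- actin_ratio_series(series_stub(rep(14, 10), 14 * r, 14 * r * cis))
  expect_equal(reorganization_interval(a)$duration,
               reorganization_interval(b)$duration)
  expect_equal(depletion_interval(a)$depletion_duration,
               depletion_interval(b)$depletion_duration)
})

test_that("floating ROIs follow per-frame geometry and propagate over gaps", {
  tl <- fixture("tl_static", function()
    generate_timelapse(scene_spec(
      seed = 13, n_t = 10, frame_interval = 5,
      actin_profile = list(burst_start = 10, burst_duration = 20,
                           burst_amplitude = 2, clearance_ratio = 0.4))))
  geoms <- segment_timelapse(tl$scene)
  expect_true(all(!vapply(geoms, is.null, logical(1))))
  rs <- extract_floating_rois(tl$scene, geoms)
  expect_false(any(rs$flagged))
  ## noise-free static conjugate: ROI masks identical across frames
  tl0 <- generate_timelapse(scene_spec(
    seed = 13, n_t = 4, frame_interval = 5, psf_sigma = 0,
    poisson_scale = 0, gaussian_sd = 0,
    actin_profile = list(burst_start = 0, burst_duration = 5,
                         burst_amplitude = 1, clearance_ratio = 0)))
  rs0 <- extract_floating_rois(tl0$scene, segment_timelapse(tl0$scene))
  expect_identical(rs0$masks[[1]]$is_band, rs0$masks[[4]]$is_band)
  expect_identical(rs0$masks[[1]]$cis_band, rs0$masks[[4]]$cis_band)
  ## cIS sits inside IS inside cell, every frame
  for (t in c(1, 6)) {
    m <- rs$masks[[t]]
    expect_true(all(m$is_band[m$cis_band]))
    expect_true(all(m$cell[m$is_band]))
  }
  ## one failed frame: flagged, masks propagated from a neighbor
  geoms_gap <- geoms
  geoms_gap[4] <- list(NULL)
  rs_gap <- extract_floating_rois(tl$scene, geoms_gap)
  expect_true(rs_gap$flagged[4])
  expect_identical(rs_gap$masks[[4]]$cell, rs$masks[[3]]$cell)
  ## too many failures: unstable conjugate
  geoms_bad <- geoms
  for (i in 1:3) geoms_bad[i] <- list(NULL)
  expect_error(extract_floating_rois(tl$scene, geoms_bad),
               class = "unstable_conjugate")
})

test_that("noise-free burst ratios match the generator profile within 1%", {
  tl <- generate_timelapse(scene_spec(
    seed = 19, n_t = 10, frame_interval = 5, psf_sigma = 0,
    poisson_scale = 0, gaussian_sd = 0,
    actin_profile = list(burst_start = 10, burst_duration = 20,
                         burst_amplitude = 2, clearance_ratio = 0.5)))
  ## measure with the ground-truth geometry: isolates the ratio arithmetic
  g_truth <- structure(list(t_cell_mask = tl$truth$cell_mask,
                            contact_segment = tl$truth$contact_segment),
                       class = "conjugate_geometry")
  rs <- extract_floating_rois(tl$scene, rep(list(g_truth), 10))
  k <- actin_ratio_series(rs)
  expect_equal(k$ratio_is_cell, tl$truth$true_ratio_is_cell, tolerance = 0.01)
  expect_equal(k$ratio_cis_is, tl$truth$true_ratio_cis_is, tolerance = 0.01)
})

test_that("sensor FI ratio normalizes at the baseline frame", {
  times <- seq(0, 60, by = 5)
  fi <- rep(3, 13)
  expect_equal(sensor_fi_ratio(fi, times, 30), rep(1, 13))
  fi2 <- c(rep(2, 7), rep(4, 6))   # doubles after the t = 30 min baseline
  r <- sensor_fi_ratio(fi2, times, 30)
  expect_equal(r[7], 1)            # frame index 7 (1-based) is t = 30 min
  expect_equal(r[13], 2)
  expect_error(sensor_fi_ratio(c(1, 0, 1), c(0, 30, 60), 30),
               class = "zero_baseline")
  expect_error(sensor_fi_ratio(rep(1, 3), c(0, 5, 10), 30),
               class = "invalid_series")
})

test_that("residence half-life is exact on closed-form exponential decay", {
  times <- seq(0, 120, by = 1)
  fi <- c(seq(0.2, 1, length.out = 11), exp(-log(2) / 20 * (1:110)))
  out <- residence_half_life(fi, times)
  expect_false(out$censored)
  expect_equal(out$half_life, 20, tolerance = 1 / 20)

  flat <- c(0.1, 1, 1, 1, 1)
  out_flat <- residence_half_life(flat, 0:4 * 5)
  expect_true(out_flat$censored)

  rising <- residence_half_life(c(1, 2, 3, 4), 0:3 * 5)
  expect_true(rising$censored)

  ## step drop straight to the half level: one frame interval
  step <- c(0, 1, 0.5, 0, 0)
  out_step <- residence_half_life(step, 0:4 * 5)
  expect_equal(out_step$half_life, 5)
})
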