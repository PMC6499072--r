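test_that("scene spec validation names the offending field", {
  expect_error(scene_spec(pixel_size = 0), class = "invalid_spec")
  expect_error(scene_spec(pixel_size = 0), "pixel_size")
  expect_error(scene_spec(true_pol_index = 1.2), "true_pol_index")
  expect_error(scene_spec(cell_radius = -1), "cell_radius")
  expect_error(scene_spec(channel_corr = -2), "channel_corr")
  expect_error(
    scene_spec(actin_profile = list(burst_start = 0, burst_duration = 10,
                                    burst_amplitude = 0.5,
                                    clearance_ratio = 0)),
    "burst_amplitude")
})

test_that("fixed seed reproduces a conjugate scene bit for bit", {
  spec <- scene_spec(seed = 9, shape = c(64, 64), cell_radius = 3,
                     apc_radius = 3.3)
  a <- generate_conjugate_scene(spec)
  b <- generate_conjugate_scene(spec)
  expect_identical(a$scene$data, b$scene$data)
  expect_identical(a$truth$organelle_centroid, b$truth$organelle_centroid)
})

test_that("limiting placement: pol index 1 puts the cloud on the contact", {
  g <- generate_conjugate_scene(scene_spec(seed = 3, true_pol_index = 1,
                                           psf_sigma = 0, poisson_scale = 0,
                                           gaussian_sd = 0))
  d <- min(sqrt((g$truth$contact_segment[, 1] -
                   g$truth$organelle_centroid[1])^2 +
                (g$truth$contact_segment[, 2] -
                   g$truth$organelle_centroid[2])^2))
  expect_lt(d, 1)
})

test_that("sidecar coordinates reproduce the target polarization index", {
  ## oracle: direct scalar projection A/B on the emitted coordinates
  for (target in c(-0.4, 0, 0.5, 0.8)) {
    g <- generate_conjugate_scene(scene_spec(seed = 17, poisson_scale = 0,
                                             gaussian_sd = 0,
                                             true_pol_index = target))
    tr <- g$truth
    b_vec <- tr$is_centroid - tr$cell_centroid
    B <- sqrt(sum(b_vec^2))
    A <- sum((tr$organelle_centroid - tr$cell_centroid) * b_vec / B)
    expect_equal(A / B, target, tolerance = 0.02 / max(abs(target), 0.02))
    expect_equal(tr$realized_pol_index, min(max(A / B, -1), 1),
                 tolerance = 1e-9)
  }
})

test_that("organelle centroid always lies inside the cell mask", {
  for (s in 1:5) {
    g <- generate_conjugate_scene(scene_spec(
      seed = s, true_pol_index = runif(1, -1, 1)))
    cen <- round(g$truth$organelle_centroid) + 1
    expect_true(g$truth$cell_mask[cen[1], cen[2]])
  }
})

test_that("timelapse profile: no clearance and no burst limits", {
  base <- list(burst_start = 5, burst_duration = 15, burst_amplitude = 2,
               clearance_ratio = 0)
  tl <- generate_timelapse(scene_spec(seed = 2, n_t = 8, frame_interval = 5,
                                      actin_profile = base))
  expect_equal(tl$truth$true_ratio_cis_is, rep(1, 8), tolerance = 1e-9)
  base$burst_amplitude <- 1
  tl <- generate_timelapse(scene_spec(seed = 2, n_t = 8, frame_interval = 5,
                                      actin_profile = base))
  expect_equal(tl$truth$true_ratio_is_cell, rep(1, 8), tolerance = 1e-9)
})

test_that("burst interval outside the time axis is rejected", {
  expect_error(generate_timelapse(scene_spec(
    seed = 1, n_t = 4, frame_interval = 5,
    actin_profile = list(burst_start = 100, burst_duration = 10,
                         burst_amplitude = 2, clearance_ratio = 0))),
    class = "invalid_spec")
  expect_error(generate_timelapse(scene_spec(seed = 1, n_t = 2)),
               class = "invalid_spec")
})

test_that("vesicle kinematics: zero speed, constant drift, determinism", {
  still <- generate_vesicle_frames(scene_spec(seed = 4, n_t = 6,
                                              n_vesicles = 3,
                                              track_speed = 0))
  expect_equal(still$truth$positions[1, , ], still$truth$positions[6, , ])

  one <- generate_vesicle_frames(scene_spec(seed = 4, n_t = 6, n_vesicles = 1,
                                            track_speed = 0.2,
                                            frame_interval_s = 1,
                                            diffusion_sd = 0))
  disp <- sqrt(diff(one$truth$positions[, 1, 1])^2 +
               diff(one$truth$positions[, 1, 2])^2) * one$truth$pixel_size
  expect_equal(disp, rep(0.2 * 1, 5), tolerance = 1e-6)

  ## 10 spots in a tight cloud: the crowding warning is part of the contract
  expect_warning(
    a <- generate_vesicle_frames(scene_spec(seed = 8, n_t = 5,
                                            n_vesicles = 10,
                                            diffusion_sd = 0.05)),
    class = "crowded_spots")
  b <- suppressWarnings(
    generate_vesicle_frames(scene_spec(seed = 8, n_t = 5, n_vesicles = 10,
                                       diffusion_sd = 0.05)))
  expect_identical(mean(a$truth$mean_speed_um_s),
                   mean(b$truth$mean_speed_um_s))
})

test_that("correlated channel pairs hit their population correlation", {
  co <- generate_correlated_channels(1, 1000, seed = 1)
  expect_equal(cor(co$ch1, co$ch2), 1, tolerance = 1e-12)
  co <- generate_correlated_channels(0, 1e5, seed = 2)
  expect_lt(abs(cor(co$ch1, co$ch2)), 0.02)
  co <- generate_correlated_channels(0.69, 1e4, seed = 3)
  expect_equal(cor(co$ch1, co$ch2), 0.69, tolerance = 0.03 / 0.69)
  expect_error(generate_correlated_channels(1.2, 100), class = "invalid_spec")
  expect_error(generate_correlated_channels(0.5, 1), class = "invalid_spec")
})

test_that("pixel/micrometer calibration round-trips exactly", {
  sc <- static_scene()$scene
  x <- c(0.37, 12, 129.5)
  expect_equal(um_to_px(px_to_um(x, sc), sc), x, tolerance = 1e-12)
})
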