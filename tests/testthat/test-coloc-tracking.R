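test_that("pearson colocalization: identity, inversion, degenerate input", {
  set.seed(2)
  ch1 <- matrix(runif(400), 20, 20)
  expect_equal(pearson_colocalization(ch1, ch1)$pearson_r, 1)
  expect_equal(pearson_colocalization(ch1, 3 - ch1)$pearson_r, -1)
  expect_error(pearson_colocalization(ch1, matrix(2, 20, 20)),
               class = "undefined_correlation")
  expect_error(pearson_colocalization(ch1, matrix(1, 10, 10)),
               class = "invalid_scene")
})

test_that("pearson matches brute-force covariance to 1e-12 on small masks", {
  set.seed(3)
  for (rep in 1:5) {
    ch1 <- matrix(rnorm(100, 50, 10), 10, 10)
    ch2 <- matrix(rnorm(100, 30, 5), 10, 10)
    mask <- matrix(runif(100) < 0.7, 10, 10)
    if (sum(mask) < 3) next
    v1 <- ch1[mask]; v2 <- ch2[mask]
    n <- length(v1)
    cov12 <- sum((v1 - mean(v1)) * (v2 - mean(v2))) / (n - 1)
    brute <- cov12 / (sqrt(sum((v1 - mean(v1))^2) / (n - 1)) *
                        sqrt(sum((v2 - mean(v2))^2) / (n - 1)))
    fl <- pearson_colocalization(ch1, ch2, mask)
    expect_equal(fl$pearson_r, brute, tolerance = 1e-12)
    expect_equal(fl$n_pixels, n)
  }
})

test_that("pearson is invariant to affine rescaling with positive gain", {
  set.seed(4)
  ch1 <- matrix(runif(256), 16, 16)
  ch2 <- matrix(runif(256), 16, 16)
  r0 <- pearson_colocalization(ch1, ch2)$pearson_r
  r1 <- pearson_colocalization(ch1 * 7 + 3, ch2)$pearson_r
  r2 <- pearson_colocalization(ch1, ch2 * 0.2 + 40)$pearson_r
  expect_equal(r1, r0, tolerance = 1e-12)
  expect_equal(r2, r0, tolerance = 1e-12)
})

test_that("generated correlated channels measure at their rho", {
  co <- generate_correlated_channels(0.69, 1e4, seed = 12)
  r <- pearson_colocalization(co$ch1, co$ch2)$pearson_r
  expect_equal(r, 0.69, tolerance = 0.03 / 0.69)
})

test_that("track linking: continuity, separation, jump termination", {
  ## one drifting spot -> one track covering all frames
  dets <- lapply(1:8, function(t) cbind(y = 10 + 0.8 * t, x = 20))
  tr <- link_tracks(dets, max_link_px = 2, min_track_len = 2)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 8)

  ## two well-separated spots -> two disjoint tracks
  dets2 <- lapply(1:5, function(t)
    rbind(c(5 + 0.5 * t, 10), c(40 + 0.5 * t, 50)))
  tr2 <- link_tracks(dets2, max_link_px = 2, min_track_len = 2)
  expect_length(tr2, 2)
  expect_true(all(vapply(tr2, nrow, integer(1)) == 5))

  ## a jump beyond max_link splits the track
  dets3 <- lapply(1:6, function(t) {
    y <- if (t <= 3) 10 + t else 50 + t
    cbind(y = y, x = 8)
  })
  tr3 <- link_tracks(dets3, max_link_px = 3, min_track_len = 2)
  expect_length(tr3, 2)
  expect_equal(vapply(tr3, nrow, integer(1)), c(3L, 3L))

  ## min_track_len filters singletons
  tr4 <- link_tracks(dets3, max_link_px = 3, min_track_len = 4)
  expect_length(tr4, 0)
})

test_that("mean speed: stationary, unit drift, short track", {
  still <- structure(data.frame(frame = 1:4, y = 2, x = 2),
                     class = c("track", "data.frame"))
  expect_equal(mean_speed(still, 0.5, 1), 0)
  drift <- structure(data.frame(frame = 1:5, y = 1:5, x = 3),
                     class = c("track", "data.frame"))
  expect_equal(mean_speed(drift, 0.5, 1), 0.5)
  single <- structure(data.frame(frame = 1, y = 1, x = 1),
                      class = c("track", "data.frame"))
  expect_error(mean_speed(single, 0.5, 1), class = "track_too_short")
})

test_that("noise-free generated drift is recovered end to end", {
  vv <- fixture("vesicle_scene", function()
    generate_vesicle_frames(scene_spec(seed = 5, n_t = 10, n_vesicles = 5,
                                       vesicle_sigma = 2.5,
                                       track_speed = 0.2,
                                       frame_interval_s = 1,
                                       psf_sigma = 0.1, poisson_scale = 0,
                                       gaussian_sd = 0)))
  geom <- segment_conjugate(vv$scene)
  dets <- lapply(1:10, function(t)
    as.matrix(detect_organelles(vv$scene, geom, t = t)$puncta[, c("y", "x")]))
  tracks <- link_tracks(dets, max_link_px = 3, min_track_len = 8)
  expect_gte(length(tracks), 3)
  sp <- track_speeds(tracks, vv$truth$pixel_size, vv$truth$frame_interval_s)
  for (s in sp$mean_speed_um_s)
    expect_equal(s, 0.2, tolerance = 0.05)
})
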