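## ring raster fixture: bright annulus, optionally dark interior
ring_image <- function(n = 64, r_out = 24, r_in = 0, rim = 6,
                       hi = 1, lo = 0.02, pixel_size = 0.2) {
  yy <- matrix(0:(n - 1), n, n)
  xx <- matrix(0:(n - 1), n, n, byrow = TRUE)
  c0 <- (n - 1) / 2
  rho <- sqrt((yy - c0)^2 + (xx - c0)^2)
  img <- matrix(lo, n, n)
  img[rho <= r_out] <- hi
  if (r_in > 0) img[rho <= r_in] <- lo
  attr(img, "pixel_size") <- pixel_size
  img
}

test_that("axis-aligned projection equals the plain max z-projection", {
  set.seed(6)
  stack <- array(runif(9 * 21 * 21), dim = c(9, 21, 21))
  scene <- image_scene(array(stack, dim = c(1, 9, 1, 21, 21)),
                       c(actin = 1), pixel_size = 1, z_step = 1)
  geom <- list(is_centroid = c(z = 4, y = 10, x = 10),
               is_axis = c(1, 0, 0), zr = 1, contact_extent = 5)
  fo <- project_interface(stack, geom, scene, slab_depth_um = 4,
                          half_size = 6)
  sub <- stack[3:7, , ]   # z = 4 +/- 2 (0-based) -> planes 3..7 (1-based)
  direct <- apply(sub, c(2, 3), max)
  expect_equal(fo[7, 7], direct[11, 11], tolerance = 1e-9)
  expect_equal(fo, direct[5:17, 5:17], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("slab beyond the stack raises interface_out_of_stack", {
  stack <- array(1, dim = c(3, 15, 15))
  scene <- image_scene(array(stack, dim = c(1, 3, 1, 15, 15)),
                       c(actin = 1), pixel_size = 1, z_step = 1)
  geom <- list(is_centroid = c(z = 1, y = 7, x = 7),
               is_axis = c(1, 0, 0), zr = 1, contact_extent = 4)
  expect_error(project_interface(stack, geom, scene, slab_depth_um = 40),
               class = "interface_out_of_stack")
})

test_that("IS area delimitation: disc area, hole filling, blank input", {
  disc <- ring_image(r_out = 20, r_in = 0)
  out <- delimit_is_area(disc)
  expect_equal(out$is_area_um2, pi * 20^2 * 0.2^2, tolerance = 0.05)
  ## annulus: interior hole included by the fill rule
  annulus <- ring_image(r_out = 20, r_in = 10)
  out_a <- delimit_is_area(annulus)
  c0 <- (nrow(annulus) + 1) / 2
  expect_true(out_a$region[c0, c0])
  expect_equal(sum(out_a$region), sum(out$region), tolerance = 0.05)
  expect_error(delimit_is_area(matrix(0, 16, 16)),
               class = "no_interface_signal")
})

test_that("ring with dark interior of half the radius gives ratio 0.25", {
  ring <- ring_image(r_out = 24, r_in = 12)
  isr <- delimit_is_area(ring)
  ip <- factin_low_area(ring, isr$region)
  expect_equal(ip$area_ratio, 0.25, tolerance = 0.02 / 0.25)
  expect_true(ip$depleted)
  ## oracle: direct pixel count of the rendered geometry
  expect_equal(ip$area_ratio, sum(ring <= 0.02 & isr$region) / sum(isr$region),
               tolerance = 1e-9)
})

test_that("uniform interior gives ratio 0; near-cutoff rings score correctly", {
  disc <- ring_image(r_out = 20, r_in = 0)
  isr <- delimit_is_area(disc)
  ip <- factin_low_area(disc, isr$region)
  expect_equal(ip$area_ratio, 0)
  expect_false(ip$depleted)
  ## interior at ~8% of the area: below the 0.1 cutoff -> not depleted
  small_hole <- ring_image(r_out = 24, r_in = ceiling(sqrt(0.08) * 24))
  isr2 <- delimit_is_area(small_hole)
  ip2 <- factin_low_area(small_hole, isr2$region)
  expect_lt(ip2$area_ratio, 0.1)
  expect_gt(ip2$area_ratio, 0.04)
  expect_false(ip2$depleted)
})

test_that("area ratio is invariant to uniform intensity scaling", {
  ring <- ring_image(r_out = 22, r_in = 11)
  isr <- delimit_is_area(ring)
  a <- factin_low_area(ring, isr$region)
  ring5 <- ring * 5
  attr(ring5, "pixel_size") <- attr(ring, "pixel_size")
  isr5 <- delimit_is_area(ring5)
  b <- factin_low_area(ring5, isr5$region)
  expect_equal(a$area_ratio, b$area_ratio, tolerance = 1e-9)
})

test_that("face-on view of a generated stack matches the rendered pattern", {
  g <- fixture("stack_scene", function()
    generate_conjugate_scene(scene_spec(
      seed = 23, shape = c(96, 96), n_z = 27, z_step = 0.4, psf_sigma = 0.1,
      true_depletion_ratio = 0.3, true_pol_index = 0.4)))
  g3 <- estimate_geometry_3d(g$scene)
  fo <- project_interface(scene_stack(g$scene, "actin"), g3, g$scene)
  ## the dark center must appear where the truth puts it: correlate the
  ## measured low mask with the truth projection via the area ratio
  isr <- delimit_is_area(fo)
  ip <- factin_low_area(fo, isr$region)
  expect_true(ip$depleted)
  expect_equal(ip$area_ratio, g$truth$realized_depletion_ratio,
               tolerance = 0.35)
})

test_that("intensity profile: flat field, ring crossings, degenerate ROI", {
  flat <- matrix(3, 32, 32)
  pr <- intensity_profile(flat, c(16, 2), c(16, 29))
  expect_equal(pr$fi, rep(3, nrow(pr)))
  ## profile across a ring diameter: exactly two local maxima
  ring <- ring_image(n = 64, r_out = 22, r_in = 14, hi = 1, lo = 0)
  pr2 <- intensity_profile(ring, c(31.5, 2), c(31.5, 61), width = 3)
  v <- pr2$fi
  is_max <- vapply(2:(length(v) - 1), function(i)
    v[i] > v[i - 1] && v[i] >= v[i + 1], logical(1))
  ## count maxima plateaus as single crossings
  runs <- rle(is_max)
  expect_equal(sum(runs$values), 2)
  expect_error(intensity_profile(flat, c(4, 4), c(4, 4)),
               class = "degenerate_roi")
})

test_that("cohort depletion percentage", {
  mk <- function(ratio) structure(list(area_ratio = ratio,
                                       depleted = ratio > 0.1,
                                       cutoff_used = 0.1),
                                  class = "interface_projection")
  res <- lapply(c(0.3, 0.05, 0.2, 0.0), mk)
  expect_equal(cohort_depletion(res), 50)
  expect_equal(cohort_depletion(lapply(c(0.3, 0.2), mk)), 100)
  expect_error(cohort_depletion(list()), class = "empty_cohort")
})
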