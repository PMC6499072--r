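## Synthetic conjugate scenes with machine-readable ground truth.
##
## Forward model: two convex bodies (T cell, APC) rendered as discs/spheres
## flattened against a shared contact plane; a punctate organelle cloud whose
## intensity-weighted centroid is steered to a target polarization index; a
## cortical actin shell with an optional burst-then-central-clearance temporal
## profile; Gaussian PSF blur; Poisson shot noise then additive Gaussian read
## noise. Every scene ships a ground-truth sidecar recorded before blur/noise.

CHANNELS <- c(apc_dye = 1L, actin = 2L, organelle = 3L, mtoc = 4L)

## fraction of the body radius between the body center and the contact plane;
## 0.6 gives a contact facet of 0.8x the body radius — at a formed synapse
## the T cell spreads onto the APC and the contact is near its widest section
FLATTEN <- 0.6

## analytic conjugate geometry on the pixel grid (0-based coordinates)
analytic_geometry_2d <- function(spec) {
  ny <- spec$shape[1]; nx <- spec$shape[2]
  r_t <- spec$cell_radius / spec$pixel_size
  r_a <- spec$apc_radius / spec$pixel_size
  x_c <- nx / 2
  cy <- (ny - 1) / 2
  cx_t <- x_c - FLATTEN * r_t
  cx_a <- x_c + FLATTEN * r_a
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  cell_mask <- (yy - cy)^2 + (xx - cx_t)^2 <= r_t^2 & xx < x_c
  apc_mask <- (yy - cy)^2 + (xx - cx_a)^2 <= r_a^2 & xx >= x_c
  if (!any(cell_mask) || !any(apc_mask))
    sp_stop("invalid_spec", "field 'cell_radius'/'apc_radius': bodies do not fit the raster")
  contact <- mask_boundary(cell_mask) & binary_dilate(apc_mask, 1)
  cc <- mask_coords(contact)
  cc <- cc[order(cc[, 1]), , drop = FALSE]
  cell_c <- mask_centroid(cell_mask)
  is_c <- weighted_centroid(cc)
  list(cell_mask = cell_mask, apc_mask = apc_mask, contact = cc,
       cell_centroid = cell_c, is_centroid = is_c,
       is_axis = unit_vector(is_c - cell_c),
       B = sqrt(sum((is_c - cell_c)^2)),
       x_c = x_c, cy = cy, r_t = r_t, yy = yy, xx = xx)
}

## 3D analogue; z scaled by z_step/pixel_size so distances are isotropic in
## lateral-pixel units. Coordinates are (z, y, x), 0-based.
analytic_geometry_3d <- function(spec) {
  ny <- spec$shape[1]; nx <- spec$shape[2]; nz <- spec$n_z
  zr <- spec$z_step / spec$pixel_size
  r_t <- spec$cell_radius / spec$pixel_size
  r_a <- spec$apc_radius / spec$pixel_size
  x_c <- nx / 2
  cy <- (ny - 1) / 2
  cz <- (nz - 1) / 2
  cx_t <- x_c - FLATTEN * r_t
  cx_a <- x_c + FLATTEN * r_a
  zz <- array(rep(0:(nz - 1), times = ny * nx), dim = c(nz, ny, nx))
  yy <- array(rep(rep(0:(ny - 1), each = nz), times = nx), dim = c(nz, ny, nx))
  xx <- array(rep(0:(nx - 1), each = nz * ny), dim = c(nz, ny, nx))
  d2_t <- ((zz - cz) * zr)^2 + (yy - cy)^2 + (xx - cx_t)^2
  d2_a <- ((zz - cz) * zr)^2 + (yy - cy)^2 + (xx - cx_a)^2
  cell_mask <- d2_t <= r_t^2 & xx < x_c
  apc_mask <- d2_a <= r_a^2 & xx >= x_c
  ## contact facet: cell voxels one lateral pixel from the plane
  facet <- cell_mask & xx >= x_c - 1.5
  w <- which(facet, arr.ind = TRUE)
  contact <- cbind(z = w[, 1] - 1, y = w[, 2] - 1, x = w[, 3] - 1)
  cw <- which(cell_mask, arr.ind = TRUE) - 1
  cell_c <- c(z = mean(cw[, 1]), y = mean(cw[, 2]), x = mean(cw[, 3]))
  is_c <- c(z = mean(contact[, 1]), y = mean(contact[, 2]),
            x = mean(contact[, 3]))
  scale3 <- c(zr, 1, 1)
  axis <- unit_vector((is_c - cell_c) * scale3)
  B <- sqrt(sum(((is_c - cell_c) * scale3)^2))
  ## interface radial coordinate in the facet plane
  rho <- sqrt((contact[, 2] - cy)^2 + ((contact[, 1] - cz) * zr)^2)
  list(cell_mask = cell_mask, apc_mask = apc_mask, contact = contact,
       cell_centroid = cell_c, is_centroid = is_c, is_axis = axis, B = B,
       x_c = x_c, cy = cy, cz = cz, zr = zr, r_t = r_t,
       zz = zz, yy = yy, xx = xx, d2_t = d2_t,
       facet = facet, facet_radius = max(rho))
}

## Gaussian spot rendering on a 2D raster; pos is Nx2 (y, x), 0-based.
render_spots <- function(ny, nx, pos, amps, sigma_px) {
  img <- matrix(0, ny, nx)
  if (is.null(pos) || nrow(pos) == 0) return(img)
  r <- ceiling(4 * sigma_px)
  for (i in seq_len(nrow(pos))) {
    y0 <- pos[i, 1]; x0 <- pos[i, 2]
    ys <- max(0, floor(y0 - r)):min(ny - 1, ceiling(y0 + r))
    xs <- max(0, floor(x0 - r)):min(nx - 1, ceiling(x0 + r))
    if (length(ys) == 0 || length(xs) == 0) next
    g <- outer(exp(-(ys - y0)^2 / (2 * sigma_px^2)),
               exp(-(xs - x0)^2 / (2 * sigma_px^2)))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amps[i] * g
  }
  img
}

## Move each point outside `allowed` (0-based coord matrix) to its nearest
## allowed pixel.
snap_into <- function(pos, allowed, mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  for (i in seq_len(nrow(pos))) {
    yi <- round(pos[i, 1]); xi <- round(pos[i, 2])
    inside <- yi >= 0 && yi < ny && xi >= 0 && xi < nx &&
      mask[yi + 1, xi + 1]
    if (!inside) {
      d2 <- (allowed[, 1] - pos[i, 1])^2 + (allowed[, 2] - pos[i, 2])^2
      pos[i, ] <- allowed[which.min(d2), ]
    }
  }
  pos
}

## Place the organelle cloud so its intensity-weighted centroid realizes the
## target polarization index; iterative recenter-and-snap keeps puncta inside
## the cell mask while driving the residual below 0.05 px.
place_cloud <- function(geom, spec) {
  target <- geom$cell_centroid + spec$true_pol_index * geom$B * geom$is_axis
  n <- spec$n_vesicles
  sig <- spec$vesicle_sigma / spec$pixel_size
  amps <- runif(n, 0.7, 1.3)
  pos <- cbind(target[1] + rnorm(n, 0, sig), target[2] + rnorm(n, 0, sig))
  allowed <- mask_coords(geom$cell_mask)
  for (iter in 1:40) {
    pos <- snap_into(pos, allowed, geom$cell_mask)
    cen <- weighted_centroid(pos, amps)
    resid <- target - cen
    if (sqrt(sum(resid^2)) < 0.05) break
    pos <- sweep(pos, 2, resid, "+")
  }
  pos <- snap_into(pos, allowed, geom$cell_mask)
  list(pos = pos, amps = amps, centroid = weighted_centroid(pos, amps))
}

## camera model: Poisson shot noise on the signal, then Gaussian read noise
apply_camera <- function(img, spec) {
  d <- dim(img)
  v <- as.numeric(img)
  if (spec$poisson_scale > 0)
    v <- rpois(length(v), v * spec$poisson_scale) / spec$poisson_scale
  if (spec$gaussian_sd > 0)
    v <- v + rnorm(length(v), 0, spec$gaussian_sd)
  array(pmax(v, 0), dim = d)
}

## base 2D channel renders (noise-free, blur-free)
render_static_channels <- function(geom, cloud, mtoc_pos, spec) {
  ny <- spec$shape[1]; nx <- spec$shape[2]
  bg <- 0.02
  apc <- bg + 0.8 * geom$apc_mask
  cortex <- geom$cell_mask & !binary_erode(geom$cell_mask, 2)
  actin <- bg + 0.3 * geom$cell_mask + 0.7 * cortex
  organelle <- bg + 0.05 * geom$cell_mask +
    render_spots(ny, nx, cloud$pos, cloud$amps,
                 0.3 / spec$pixel_size)
  mtoc <- bg + 0.05 * geom$cell_mask +
    render_spots(ny, nx, rbind(mtoc_pos), 1.2, 0.35 / spec$pixel_size)
  list(apc_dye = apc, actin = actin, organelle = organelle, mtoc = mtoc)
}

finish_frame <- function(channels, spec) {
  blur <- spec$psf_sigma / spec$pixel_size
  lapply(channels, function(ch) apply_camera(gaussian_blur(ch, blur), spec))
}

assemble_scene <- function(frames, spec) {
  ## frames: list over t of list over z of named channel list
  n_t <- length(frames); n_z <- length(frames[[1]])
  ny <- spec$shape[1]; nx <- spec$shape[2]
  data <- array(0, dim = c(n_t, n_z, length(CHANNELS), ny, nx))
  for (t in seq_len(n_t)) for (z in seq_len(n_z))
    for (ch in names(CHANNELS))
      data[t, z, CHANNELS[[ch]], , ] <- frames[[t]][[z]][[ch]]
  image_scene(data, CHANNELS, spec$pixel_size, spec$z_step,
              spec$frame_interval)
}

#' Generate a synthetic T cell/APC conjugate scene
#'
#' Renders a four-channel (APC dye, actin, organelle, MTOC) static scene —
#' 2D when `n_z == 1`, a z-stack otherwise — together with ground truth
#' recorded before blur and noise. The organelle cloud centroid is placed so
#' that its noise-free polarization index equals `spec$true_pol_index`
#' (within 0.02).
#'
#' @param spec a [scene_spec()].
#' @return list with elements `scene` ([image_scene]) and `truth`
#'   (ground-truth list: masks, contact pixels, centroids, realized
#'   polarization index, interface geometry for stacks).
#' @export
generate_conjugate_scene <- function(spec) {
  spec <- validate_scene_spec(spec)
  set.seed(spec$seed)
  if (spec$n_z == 1L) {
    geom <- analytic_geometry_2d(spec)
    cloud <- place_cloud(geom, spec)
    mtoc_pos <- cloud$centroid + rnorm(2, 0, 0.5 / spec$pixel_size)
    mtoc_pos <- snap_into(rbind(mtoc_pos), mask_coords(geom$cell_mask),
                          geom$cell_mask)[1, ]
    clean <- render_static_channels(geom, cloud, mtoc_pos, spec)
    frames <- list(list(finish_frame(clean, spec)))
    scene <- assemble_scene(frames, spec)
    a <- sum((cloud$centroid - geom$cell_centroid) * geom$is_axis)
    truth <- list(
      cell_mask = geom$cell_mask, apc_mask = geom$apc_mask,
      contact_segment = geom$contact,
      cell_centroid = geom$cell_centroid, is_centroid = geom$is_centroid,
      is_axis = geom$is_axis, B = geom$B,
      organelle_centroid = cloud$centroid, mtoc_position = mtoc_pos,
      spot_positions = cloud$pos, spot_amplitudes = cloud$amps,
      true_pol_index = spec$true_pol_index,
      realized_pol_index = clamp(a / geom$B, -1, 1),
      pixel_size = spec$pixel_size)
    return(list(scene = scene, truth = truth))
  }
  generate_conjugate_stack(spec)
}

## z-stack variant: spherical bodies, cortical actin shell, dSMAC-like bright
## interface rim with an optional central F-actin-low region of target area
## fraction `true_depletion_ratio`. The stack emulates fixed, phalloidin-like
## F-actin staining: cytosolic (monomeric) actin contributes almost nothing,
## the cortical shell is bright, and the cleared center drops to cytosol
## level — near-complete central F-actin loss.
generate_conjugate_stack <- function(spec) {
  geom <- analytic_geometry_3d(spec)
  ny <- spec$shape[1]; nx <- spec$shape[2]; nz <- spec$n_z
  bg <- 0.02
  cytosol <- 0.08
  shell <- geom$cell_mask & geom$d2_t >= (geom$r_t - 2)^2
  rho <- sqrt((geom$yy - geom$cy)^2 + ((geom$zz - geom$cz) * geom$zr)^2)
  ## cortical facet band: ~0.5 um of F-actin at the contact
  facet_th <- 0.5 / spec$pixel_size
  facet <- geom$cell_mask & geom$xx >= geom$x_c - facet_th
  ## interface radius of the projected facet, so the cleared-center area
  ## fraction of the projection equals the requested depletion ratio
  r_is <- max(rho[facet])
  actin <- bg + cytosol * geom$cell_mask + (1 - cytosol) * shell
  actin[facet] <- 1
  dep <- spec$true_depletion_ratio
  low_zone <- array(FALSE, dim = dim(actin))
  if (dep > 0) {
    low_zone <- facet & rho <= sqrt(dep) * r_is
    actin[low_zone] <- bg + cytosol
  }
  apc <- bg + 0.8 * geom$apc_mask
  ## organelle cloud in 3D, centered near the mid-plane
  sig <- spec$vesicle_sigma / spec$pixel_size
  target <- geom$cell_centroid + spec$true_pol_index * geom$B *
    geom$is_axis / c(geom$zr, 1, 1)
  n <- spec$n_vesicles
  amps <- runif(n, 0.7, 1.3)
  pos <- cbind(target[1] + rnorm(n, 0, sig / geom$zr),
               target[2] + rnorm(n, 0, sig),
               target[3] + rnorm(n, 0, sig))
  w <- which(geom$cell_mask, arr.ind = TRUE) - 1
  for (i in seq_len(n)) {
    zi <- round(pos[i, 1]); yi <- round(pos[i, 2]); xi <- round(pos[i, 3])
    ok <- zi >= 0 && zi < nz && yi >= 0 && yi < ny && xi >= 0 && xi < nx &&
      geom$cell_mask[zi + 1, yi + 1, xi + 1]
    if (!ok) {
      d2 <- ((w[, 1] - pos[i, 1]) * geom$zr)^2 + (w[, 2] - pos[i, 2])^2 +
        (w[, 3] - pos[i, 3])^2
      pos[i, ] <- w[which.min(d2), ]
    }
  }
  cen <- c(sum(amps * pos[, 1]), sum(amps * pos[, 2]),
           sum(amps * pos[, 3])) / sum(amps)
  mtoc_pos <- cen
  spot_sig <- 0.3 / spec$pixel_size
  blur <- spec$psf_sigma / spec$pixel_size
  frames_z <- vector("list", nz)
  for (z in seq_len(nz)) {
    zc0 <- z - 1
    dzs_org <- exp(-((pos[, 1] - zc0) * geom$zr)^2 / (2 * spot_sig^2))
    org <- bg + 0.05 * geom$cell_mask[z, , ] +
      render_spots(ny, nx, pos[, 2:3, drop = FALSE], amps * dzs_org, spot_sig)
    dz_mtoc <- exp(-((mtoc_pos[1] - zc0) * geom$zr)^2 / (2 * (0.35 / spec$pixel_size)^2))
    mt <- bg + 0.05 * geom$cell_mask[z, , ] +
      render_spots(ny, nx, rbind(mtoc_pos[2:3]), 1.2 * dz_mtoc,
                   0.35 / spec$pixel_size)
    chans <- list(apc_dye = matrix(apc[z, , ], ny, nx),
                  actin = matrix(actin[z, , ], ny, nx),
                  organelle = org, mtoc = mt)
    chans <- lapply(chans, function(m) gaussian_blur(m, blur))
    frames_z[[z]] <- lapply(chans, function(m) apply_camera(m, spec))
  }
  scene <- assemble_scene(list(frames_z), spec)
  ## ground-truth interface projection (facet collapsed along x onto (z, y))
  facet_zy <- apply(facet, c(1, 2), any)
  low_zy <- apply(low_zone, c(1, 2), any)
  a <- sum(((cen - geom$cell_centroid) * c(geom$zr, 1, 1)) * geom$is_axis)
  truth <- list(
    cell_mask = geom$cell_mask, apc_mask = geom$apc_mask,
    contact_segment = geom$contact,
    cell_centroid = geom$cell_centroid, is_centroid = geom$is_centroid,
    is_axis = geom$is_axis, B = geom$B, zr = geom$zr,
    organelle_centroid = cen, mtoc_position = mtoc_pos,
    spot_positions = pos, spot_amplitudes = amps,
    true_pol_index = spec$true_pol_index,
    realized_pol_index = clamp(a / geom$B, -1, 1),
    interface_radius = geom$facet_radius,
    facet_projection = facet_zy, low_projection = low_zy,
    true_depletion_ratio = spec$true_depletion_ratio,
    realized_depletion_ratio = sum(low_zy) / sum(facet_zy),
    pixel_size = spec$pixel_size)
  list(scene = scene, truth = truth)
}

#' Generate a synthetic time-lapse of actin reorganization at the synapse
#'
#' The actin channel starts spatially uniform over the T cell (ratio
#' baseline 1), the synaptic band is multiplied by `burst_amplitude` during
#' the burst interval, and the central band is multiplied by
#' `1 - clearance_ratio` during the clearance interval (default: the burst
#' interval). True per-frame IS/cell and cIS/IS mean-intensity ratios —
#' measured on the noise-free render with the ground-truth ROIs — are
#' recorded in the sidecar.
#'
#' @param spec a [scene_spec()] with `n_t >= 3` and `actin_profile` set.
#' @param band_depth_um synaptic band depth, micrometers.
#' @param central_fraction central fraction of the contact arc defining the
#'   cIS band.
#' @return list with `scene` and `truth` (ROI masks, per-frame true ratios,
#'   frame times in minutes).
#' @export
generate_timelapse <- function(spec, band_depth_um = 1.5,
                               central_fraction = 0.5) {
  spec <- validate_scene_spec(spec)
  if (spec$n_t < 3) sp_stop("invalid_spec", "field 'n_t' must be >= 3")
  ap <- spec$actin_profile
  if (is.null(ap)) sp_stop("invalid_spec", "field 'actin_profile' must be set")
  times <- (seq_len(spec$n_t) - 1) * spec$frame_interval
  span <- max(times)
  if (ap$burst_start > span || ap$burst_start + ap$burst_duration > span)
    sp_stop("invalid_spec",
            "field 'actin_profile': burst interval outside the time axis")
  set.seed(spec$seed)
  geom <- analytic_geometry_2d(spec)
  cloud <- place_cloud(geom, spec)
  mtoc_pos <- snap_into(rbind(cloud$centroid), mask_coords(geom$cell_mask),
                        geom$cell_mask)[1, ]
  ny <- spec$shape[1]; nx <- spec$shape[2]
  bg <- 0.02
  ## ROI masks mirroring the floating-ROI definitions
  band <- is_band_mask(geom$cell_mask, geom$contact,
                       band_depth_um / spec$pixel_size)
  cis <- cis_band_mask(geom$cell_mask, geom$contact,
                       band_depth_um / spec$pixel_size, central_fraction)
  in_burst <- times >= ap$burst_start &
    times < ap$burst_start + ap$burst_duration
  in_clear <- times >= ap$clearance_start &
    times < ap$clearance_start + ap$clearance_duration
  organelle0 <- bg + 0.05 * geom$cell_mask +
    render_spots(ny, nx, cloud$pos, cloud$amps, 0.3 / spec$pixel_size)
  mtoc0 <- bg + 0.05 * geom$cell_mask +
    render_spots(ny, nx, rbind(mtoc_pos), 1.2, 0.35 / spec$pixel_size)
  apc0 <- bg + 0.8 * geom$apc_mask
  true_is_cell <- numeric(spec$n_t)
  true_cis_is <- numeric(spec$n_t)
  frames <- vector("list", spec$n_t)
  for (t in seq_len(spec$n_t)) {
    actin <- bg + 0.5 * geom$cell_mask
    if (in_burst[t]) actin[band] <- actin[band] * ap$burst_amplitude
    if (in_clear[t]) actin[cis] <- actin[cis] * (1 - ap$clearance_ratio)
    true_is_cell[t] <- mean(actin[band]) / mean(actin[geom$cell_mask])
    true_cis_is[t] <- mean(actin[cis]) / mean(actin[band])
    frames[[t]] <- list(finish_frame(
      list(apc_dye = apc0, actin = actin, organelle = organelle0,
           mtoc = mtoc0), spec))
  }
  scene <- assemble_scene(frames, spec)
  truth <- list(
    cell_mask = geom$cell_mask, apc_mask = geom$apc_mask,
    contact_segment = geom$contact,
    cell_centroid = geom$cell_centroid, is_centroid = geom$is_centroid,
    is_band = band, cis_band = cis, times_min = times,
    true_ratio_is_cell = true_is_cell, true_ratio_cis_is = true_cis_is,
    burst_frames = which(in_burst), clearance_frames = which(in_clear),
    organelle_centroid = cloud$centroid,
    true_pol_index = spec$true_pol_index,
    pixel_size = spec$pixel_size)
  list(scene = scene, truth = truth)
}

#' Generate a synthetic vesicle-tracking video
#'
#' Point-like organelle spots drift toward the synapse at `track_speed`
#' (micrometers per second; frames are `frame_interval_s` apart) with
#' optional isotropic diffusion, on a dim cell background. True per-frame
#' positions and per-track mean speeds are recorded.
#'
#' @param spec a [scene_spec()]; `n_t` frames are rendered.
#' @return list with `scene` and `truth` (`positions`: array
#'   `[n_t, n_spots, 2]` of 0-based (y, x), `mean_speed_um_s` per spot).
#' @export
generate_vesicle_frames <- function(spec) {
  spec <- validate_scene_spec(spec)
  if (spec$n_t < 2) sp_stop("invalid_spec", "field 'n_t' must be >= 2")
  set.seed(spec$seed)
  geom <- analytic_geometry_2d(spec)
  n <- max(1L, spec$n_vesicles)
  interior <- binary_erode(geom$cell_mask, 3)
  allowed <- mask_coords(if (any(interior)) interior else geom$cell_mask)
  ## start distal so drift toward the synapse stays inside the cell
  start_center <- geom$cell_centroid - 0.4 * geom$B * geom$is_axis
  sig <- max(spec$vesicle_sigma, 0.3) / spec$pixel_size
  pos <- cbind(start_center[1] + rnorm(n, 0, sig),
               start_center[2] + rnorm(n, 0, sig))
  pos <- snap_into(pos, allowed, if (any(interior)) interior else geom$cell_mask)
  if (n > 1) {
    dmat <- as.matrix(stats::dist(pos))
    diag(dmat) <- Inf
    if (min(dmat) < 2)
      sp_warn("crowded_spots",
              "spot spacing below linking resolution (< 2 px)")
  }
  step_px <- spec$track_speed * spec$frame_interval_s / spec$pixel_size
  diff_px <- spec$diffusion_sd / spec$pixel_size
  amps <- runif(n, 0.8, 1.2)
  positions <- array(NA_real_, dim = c(spec$n_t, n, 2))
  frames <- vector("list", spec$n_t)
  bg <- 0.02
  for (t in seq_len(spec$n_t)) {
    if (t > 1) {
      pos <- pos + matrix(step_px * geom$is_axis, n, 2, byrow = TRUE)
      if (diff_px > 0) pos <- pos + matrix(rnorm(2 * n, 0, diff_px), n, 2)
      pos <- snap_into(pos, allowed,
                       if (any(interior)) interior else geom$cell_mask)
    }
    positions[t, , ] <- pos
    org <- bg + 0.05 * geom$cell_mask +
      render_spots(spec$shape[1], spec$shape[2], pos, amps,
                   0.3 / spec$pixel_size)
    chans <- list(apc_dye = bg + 0.8 * geom$apc_mask,
                  actin = bg + 0.3 * geom$cell_mask +
                    0.7 * (geom$cell_mask & !binary_erode(geom$cell_mask, 2)),
                  organelle = org,
                  mtoc = matrix(bg, spec$shape[1], spec$shape[2]))
    frames[[t]] <- list(finish_frame(chans, spec))
  }
  scene <- assemble_scene(frames, spec)
  ## true mean speed per spot from the recorded positions
  speeds <- vapply(seq_len(n), function(i) {
    p <- positions[, i, , drop = FALSE]
    d <- sqrt(diff(p[, 1, 1])^2 + diff(p[, 1, 2])^2)
    mean(d) * spec$pixel_size / spec$frame_interval_s
  }, numeric(1))
  truth <- list(cell_mask = geom$cell_mask, positions = positions,
                mean_speed_um_s = speeds, is_axis = geom$is_axis,
                frame_interval_s = spec$frame_interval_s,
                pixel_size = spec$pixel_size)
  list(scene = scene, truth = truth)
}

#' Generate a pair of intensity rasters with known pixel-wise correlation
#'
#' Bivariate Gaussian pixel pairs with population correlation `rho`, shifted
#' and scaled to nonnegative intensities — fixtures for fluorogram
#' colocalization.
#'
#' @param rho population Pearson correlation in \[-1, 1\].
#' @param n_pixels number of pixel pairs (>= 2).
#' @param seed RNG seed.
#' @return list with numeric vectors `ch1`, `ch2` of length `n_pixels`.
#' @export
generate_correlated_channels <- function(rho, n_pixels, seed = 1L) {
  if (!is.numeric(rho) || abs(rho) > 1)
    sp_stop("invalid_spec", "field 'rho' must lie in [-1, 1]")
  if (n_pixels < 2) sp_stop("invalid_spec", "field 'n_pixels' must be >= 2")
  set.seed(seed)
  z1 <- rnorm(n_pixels)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_pixels)
  list(ch1 = pmax(100 + 15 * z1, 0), ch2 = pmax(100 + 15 * z2, 0))
}
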