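## Face-on (en face) views of the synaptic interface from z-stacks, the
## F-actin-low central area ratio, and intensity plot profiles.

## trilinear interpolation into a [z, y, x] stack at 0-based coordinates;
## points outside the volume return `fill`
trilinear <- function(stack, z, y, x, fill = 0) {
  d <- dim(stack)
  out <- numeric(length(z))
  inside <- z >= 0 & z <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    x >= 0 & x <= d[3] - 1
  if (!any(inside)) return(out + fill)
  z <- z[inside]; y <- y[inside]; x <- x[inside]
  z0 <- pmin(floor(z), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  x0 <- pmin(floor(x), d[3] - 2)
  z0 <- pmax(z0, 0); y0 <- pmax(y0, 0); x0 <- pmax(x0, 0)
  fz <- z - z0; fy <- y - y0; fx <- x - x0
  g <- function(dz, dy, dx)
    ## upper-corner indices are clamped: their weights vanish on singleton
    ## axes but R still evaluates the lookup
    stack[cbind(pmin(z0 + dz, d[1] - 1) + 1, pmin(y0 + dy, d[2] - 1) + 1,
                pmin(x0 + dx, d[3] - 1) + 1)]
  v <-
    g(0, 0, 0) * (1 - fz) * (1 - fy) * (1 - fx) +
    g(1, 0, 0) * fz * (1 - fy) * (1 - fx) +
    g(0, 1, 0) * (1 - fz) * fy * (1 - fx) +
    g(0, 0, 1) * (1 - fz) * (1 - fy) * fx +
    g(1, 1, 0) * fz * fy * (1 - fx) +
    g(1, 0, 1) * fz * (1 - fy) * fx +
    g(0, 1, 1) * (1 - fz) * fy * fx +
    g(1, 1, 1) * fz * fy * fx
  res <- numeric(length(inside)) + fill
  res[inside] <- v
  res
}

## one-voxel 26-neighborhood dilation via array shifts
dilate3d_1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    sh <- array(FALSE, dim = d)
    zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
    sh[zs, ys, xs] <- mask[zs - dz, ys - dy, xs - dx]
    out <- out | sh
  }
  out
}

#' Estimate 3D conjugate geometry from a z-stack scene
#'
#' Otsu thresholds the APC and T-cell channels in 3D, keeps the largest
#' components, and takes the contact as T-cell voxels adjacent to the APC.
#' The z axis is scaled by `z_step / pixel_size` before centroid/axis
#' computation so distances are isotropic in lateral-pixel units.
#'
#' @param scene an [image_scene] with a z axis.
#' @param t time index.
#' @param t_cell_channel channel role for the T-cell body.
#' @return list: `cell_centroid`, `is_centroid` (0-based (z, y, x) indices),
#'   `is_axis` (unit, scaled space), `zr` anisotropy factor, `contact`
#'   voxel coordinates, `contact_extent` (max contact radius, pixels).
#' @export
estimate_geometry_3d <- function(scene, t = 1L, t_cell_channel = "actin") {
  apc <- scene_stack(scene, "apc_dye", t)
  tc <- scene_stack(scene, t_cell_channel, t)
  if (diff(range(apc)) == 0) sp_stop("no_conjugate", "blank APC channel")
  apc_mask <- largest_component(apc > otsu_threshold(apc))
  tc_fg <- tc > otsu_threshold(tc) & !apc_mask
  cell_mask <- largest_component(tc_fg)
  if (!any(cell_mask)) sp_stop("no_cell", "no T-cell component")
  ## contact: cell voxels with an APC voxel among their 26-neighbors
  zr <- scene$z_step / scene$pixel_size
  contact_mask <- cell_mask & dilate3d_1(apc_mask)
  if (!any(contact_mask)) sp_stop("no_conjugate", "empty 3D contact")
  w_cell <- which(cell_mask, arr.ind = TRUE)
  contact <- which(contact_mask, arr.ind = TRUE) - 1
  cell_c <- colMeans(w_cell) - 1
  is_c <- colMeans(contact)
  scale3 <- c(zr, 1, 1)
  axis <- unit_vector((is_c - cell_c) * scale3)
  rel <- sweep(contact, 2, is_c)
  extent <- sqrt(max(rowSums(sweep(rel, 2, scale3, "*")^2)))
  list(cell_mask = cell_mask, apc_mask = apc_mask,
       cell_centroid = stats::setNames(cell_c, c("z", "y", "x")),
       is_centroid = stats::setNames(is_c, c("z", "y", "x")),
       is_axis = axis, zr = zr, contact = contact, contact_extent = extent)
}

#' Face-on projection of the synaptic interface
#'
#' Reslices a z-stack along the IS normal (the axis from the cell center
#' through the IS centroid) and maximum-projects a slab of `slab_depth_um`
#' centered on the contact plane, yielding a 2D view of the synapse as seen
#' from the T cell. Anisotropy is corrected by scaling z before rotation;
#' sampling is trilinear.
#'
#' @param stack numeric `[z, y, x]` array (one channel, one time point).
#' @param geometry output of [estimate_geometry_3d()] (or generator truth
#'   with the same fields).
#' @param scene the owning [image_scene] (calibration).
#' @param slab_depth_um slab thickness, micrometers.
#' @param half_size half-width of the face-on raster, pixels; defaults to
#'   1.4x the contact extent.
#' @return numeric square matrix (face-on view), attribute `pixel_size`.
#' @export
project_interface <- function(stack, geometry, scene, slab_depth_um = 1.5,
                              half_size = NULL) {
  d <- dim(stack)
  if (d[1] < 3) sp_stop("invalid_scene", "need a z-stack with >= 3 planes")
  zr <- geometry$zr
  n <- geometry$is_axis
  half_slab_px <- (slab_depth_um / scene$pixel_size) / 2
  ## slab must stay inside the volume along the normal
  center <- as.numeric(geometry$is_centroid) * c(zr, 1, 1)
  for (s in c(-half_slab_px, half_slab_px)) {
    p <- (center + s * n) / c(zr, 1, 1)
    if (p[1] < 0 || p[1] > d[1] - 1 || p[2] < 0 || p[2] > d[2] - 1 ||
        p[3] < 0 || p[3] > d[3] - 1)
      sp_stop("interface_out_of_stack",
              "projection slab extends outside the stack")
  }
  ## orthonormal in-plane basis; u seeded from whichever axis is least
  ## aligned with the normal so the construction never degenerates
  seed_axis <- diag(3)[, which.min(abs(n))]
  u <- unit_vector(seed_axis - sum(seed_axis * n) * n)
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  if (is.null(half_size))
    half_size <- max(8L, ceiling(1.4 * (geometry$contact_extent %||% 10)))
  ab <- seq(-half_size, half_size)
  grid <- as.matrix(expand.grid(a = ab, b = ab))
  ss <- seq(-half_slab_px, half_slab_px, length.out =
              max(3L, ceiling(2 * half_slab_px) + 1L))
  faceon <- matrix(-Inf, length(ab), length(ab))
  for (s in ss) {
    pts <- sweep(grid[, 1, drop = FALSE] %*% rbind(u) +
                   grid[, 2, drop = FALSE] %*% rbind(v), 2,
                 center + s * n, "+")
    vals <- trilinear(stack, pts[, 1] / zr, pts[, 2], pts[, 3])
    faceon <- pmax(faceon, matrix(vals, length(ab), length(ab)))
  }
  attr(faceon, "pixel_size") <- scene$pixel_size
  faceon
}

#' Delimit the IS area from a face-on actin view
#'
#' The synapse boundary is the outer edge of the F-actin signal (the dSMAC
#' ring): Otsu threshold, largest component, morphological closing (radius
#' 2 px), hole filling.
#'
#' @param faceon face-on actin raster (from [project_interface()]).
#' @param pixel_size micrometers per pixel (defaults to the raster's
#'   attribute).
#' @return list: `region` logical mask, `is_area_um2`.
#' @export
delimit_is_area <- function(faceon, pixel_size = attr(faceon, "pixel_size")) {
  if (is.null(pixel_size)) pixel_size <- 1
  if (diff(range(faceon)) == 0)
    sp_stop("no_interface_signal", "no above-threshold pixels")
  fg <- faceon > otsu_threshold(faceon)
  if (!any(fg)) sp_stop("no_interface_signal", "no above-threshold pixels")
  region <- fill_holes(binary_closing(largest_component(fg), 2))
  list(region = region, is_area_um2 = sum(region) * pixel_size^2)
}

#' Central F-actin-low area ratio of the synaptic interface
#'
#' The F-actin-low region is the largest contiguous set of pixels inside
#' the IS region darker than `rim_fraction` times the median intensity of
#' the dSMAC rim (the outer band of the region), whose centroid lies within
#' half the region's equivalent radius of the region centroid. The ratio of
#' its area to the IS area scores central actin clearance; ratios strictly
#' above `cutoff` (default 0.1) are classified as depleted.
#'
#' @param faceon face-on actin raster.
#' @param is_region logical mask from [delimit_is_area()].
#' @param cutoff area-ratio cutoff for the depleted call.
#' @param rim_fraction low-intensity threshold as a fraction of the rim
#'   median.
#' @param pixel_size micrometers per pixel.
#' @return `interface_projection` list: `is_area_um2`, `factin_low_area_um2`,
#'   `area_ratio`, `depleted`, `cutoff_used`.
#' @export
factin_low_area <- function(faceon, is_region, cutoff = 0.1,
                            rim_fraction = 0.5,
                            pixel_size = attr(faceon, "pixel_size")) {
  if (is.null(pixel_size)) pixel_size <- 1
  if (!any(is_region)) sp_stop("no_interface_signal", "empty IS region")
  area_px <- sum(is_region)
  r_eq <- sqrt(area_px / pi)
  rim_width <- max(2, 0.2 * r_eq)
  rim <- is_region & !binary_erode(is_region, rim_width)
  rim_median <- median(faceon[rim])
  low <- is_region & faceon < rim_fraction * rim_median
  ratio <- 0
  low_area <- 0
  if (any(low)) {
    lab <- label_components(low)
    center <- mask_centroid(is_region)
    sizes <- tabulate(lab[lab > 0L])
    for (k in order(sizes, decreasing = TRUE)) {
      comp <- matrix(lab == k, nrow(lab), ncol(lab))
      cen <- mask_centroid(comp)
      if (sqrt(sum((cen - center)^2)) <= r_eq / 2) {
        low_area <- sizes[k]
        ratio <- sizes[k] / area_px
        break
      }
    }
  }
  structure(list(is_area_um2 = area_px * pixel_size^2,
                 factin_low_area_um2 = low_area * pixel_size^2,
                 area_ratio = ratio, depleted = ratio > cutoff,
                 cutoff_used = cutoff),
            class = "interface_projection")
}

#' Intensity plot profile along a rectangular ROI
#'
#' Mean intensity across the ROI's short axis at each position along its
#' long axis, the standard "plot profile" readout.
#'
#' @param img 2D intensity raster.
#' @param from,to 0-based (y, x) endpoints of the profile line.
#' @param width ROI width (short axis), pixels.
#' @return data frame: `position_px`, `position_um` (if the raster carries a
#'   `pixel_size` attribute), `fi`.
#' @export
intensity_profile <- function(img, from, to, width = 3) {
  from <- as.numeric(from); to <- as.numeric(to)
  len <- sqrt(sum((to - from)^2))
  if (len < 1) sp_stop("degenerate_roi", "profile ROI shorter than 2 pixels")
  u <- (to - from) / len
  v <- c(-u[2], u[1])
  n_pos <- floor(len) + 1L
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = max(1L, width))
  stack3 <- array(img, dim = c(1L, dim(img)))
  fi <- vapply(seq_len(n_pos) - 1L, function(s) {
    pts <- t(vapply(offs, function(o) from + s * u + o * v, numeric(2)))
    mean(trilinear(stack3, rep(0, nrow(pts)), pts[, 1], pts[, 2]))
  }, numeric(1))
  px <- seq_len(n_pos) - 1L
  ps <- attr(img, "pixel_size")
  data.frame(position_px = px,
             position_um = if (is.null(ps)) px else px * ps,
             fi = fi)
}

#' Percent of synapses scored as F-actin depleted in a cohort
#'
#' @param results list of `interface_projection` objects with one cutoff.
#' @return percentage (0-100) with `depleted == TRUE`.
#' @export
cohort_depletion <- function(results) {
  if (length(results) == 0L) sp_stop("empty_cohort", "no results")
  cutoffs <- vapply(results, `[[`, numeric(1), "cutoff_used")
  if (length(unique(cutoffs)) > 1L)
    sp_stop("mixed_cutoffs", "results use different cutoffs")
  flags <- vapply(results, `[[`, logical(1), "depleted")
  100 * sum(flags) / length(flags)
}
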