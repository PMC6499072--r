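## Time-resolved actin reorganization at the synapse from floating ROIs.
##
## Three nested ROIs per frame: the whole cell, the synaptic band (IS) of a
## configurable depth inward from the contact segment, and the central
## synaptic band (cIS), the central fraction of the contact arc. The two
## tracked statistics are mean-FI ratios IS/cell and cIS/IS per frame.

## synaptic band: cell pixels within `depth_px` of the contact segment
is_band_mask <- function(cell_mask, contact, depth_px) {
  coords <- mask_coords(cell_mask)
  d <- dist_to_set(coords, contact[, c(1, 2), drop = FALSE])
  keep <- coords[d <= depth_px, , drop = FALSE]
  out <- matrix(FALSE, nrow(cell_mask), ncol(cell_mask))
  out[cbind(keep[, 1] + 1, keep[, 2] + 1)] <- TRUE
  out
}

## central band: band pixels whose nearest contact pixel lies on the central
## fraction of the contact arc (contact pixels ordered along the boundary) —
## nearest-pixel assignment keeps cIS a true central slice of the IS band
cis_band_mask <- function(cell_mask, contact, depth_px, central_fraction) {
  n <- nrow(contact)
  lo <- floor(n * (1 - central_fraction) / 2) + 1L
  hi <- ceiling(n * (1 + central_fraction) / 2)
  coords <- mask_coords(cell_mask)
  ct <- contact[, c(1, 2), drop = FALSE]
  nearest <- integer(nrow(coords))
  dmin <- numeric(nrow(coords))
  block <- max(1L, floor(1e6 / max(1L, n)))
  for (i0 in seq(1L, nrow(coords), by = block)) {
    i1 <- min(nrow(coords), i0 + block - 1L)
    dy <- outer(coords[i0:i1, 1], ct[, 1], "-")
    dx <- outer(coords[i0:i1, 2], ct[, 2], "-")
    d2 <- dy * dy + dx * dx
    nearest[i0:i1] <- apply(d2, 1, which.min)
    dmin[i0:i1] <- sqrt(d2[cbind(seq_len(i1 - i0 + 1L), nearest[i0:i1])])
  }
  keep <- coords[dmin <= depth_px & nearest >= lo & nearest <= hi, ,
                 drop = FALSE]
  out <- matrix(FALSE, nrow(cell_mask), ncol(cell_mask))
  out[cbind(keep[, 1] + 1, keep[, 2] + 1)] <- TRUE
  out
}

#' Segment every frame of a time-lapse, tolerating per-frame failures
#'
#' @param scene an [image_scene] with a time axis.
#' @param config a [segmentation_config()].
#' @return list of `conjugate_geometry` (or `NULL` where segmentation
#'   failed), one per frame.
#' @export
segment_timelapse <- function(scene, config = segmentation_config()) {
  n_t <- scene_dims(scene)$t
  lapply(seq_len(n_t), function(t) {
    tryCatch(suppressWarnings(segment_conjugate(scene, t = t, config = config)),
             synapsepol_error = function(e) NULL)
  })
}

#' Extract floating ROIs and their mean fluorescence intensities
#'
#' ROIs are recomputed ("float") every frame from that frame's segmentation.
#' Frames whose segmentation failed inherit the masks of the nearest
#' segmented frame and are flagged; if more than 20% of frames fail the
#' conjugate is deemed unstable.
#'
#' @param scene an [image_scene] time-lapse (>= 3 frames).
#' @param geometries per-frame list from [segment_timelapse()] (or ground
#'   truth); `NULL` entries mark failed frames.
#' @param channel channel role whose mean FI is measured (default actin).
#' @param band_depth_um IS band depth inward from the contact, micrometers.
#' @param central_fraction central fraction of the contact arc for the cIS.
#' @return `roi_series` list: `times_min`, per-frame mean FIs `cell_fi`,
#'   `is_fi`, `cis_fi`, `flagged` (logical), and the per-frame `masks`.
#' @export
extract_floating_rois <- function(scene, geometries, channel = "actin",
                                  band_depth_um = 1.5,
                                  central_fraction = 0.5) {
  n_t <- scene_dims(scene)$t
  if (n_t < 3) sp_stop("invalid_scene", "need >= 3 frames")
  ok <- !vapply(geometries, is.null, logical(1))
  if (mean(ok) < 0.8)
    sp_stop("unstable_conjugate",
            sprintf("conjugate lost in %d/%d frames", sum(!ok), n_t))
  idx_ok <- which(ok)
  nearest <- vapply(seq_len(n_t), function(t)
    idx_ok[which.min(abs(idx_ok - t))], integer(1))
  depth_px <- band_depth_um / scene$pixel_size
  times <- (seq_len(n_t) - 1) * scene$frame_interval
  cell_fi <- is_fi <- cis_fi <- numeric(n_t)
  masks <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    g <- geometries[[nearest[t]]]
    cell <- g$t_cell_mask %||% g$cell_mask
    band <- is_band_mask(cell, g$contact_segment, depth_px)
    cis <- cis_band_mask(cell, g$contact_segment, depth_px, central_fraction)
    img <- scene_frame(scene, channel, t = t)
    cell_fi[t] <- mean(img[cell])
    is_fi[t] <- mean(img[band])
    cis_fi[t] <- mean(img[cis])
    masks[[t]] <- list(cell = cell, is_band = band, cis_band = cis)
  }
  structure(list(times_min = times, cell_fi = cell_fi, is_fi = is_fi,
                 cis_fi = cis_fi, flagged = !ok, masks = masks),
            class = "roi_series")
}

#' Per-frame actin intensity ratios
#'
#' `ratio_is_cell[t] = mean FI(IS) / mean FI(cell)` and
#' `ratio_cis_is[t] = mean FI(cIS) / mean FI(IS)`. Frames with a zero
#' denominator get `NA` with a warning and are excluded from the interval
#' summaries.
#'
#' @param series a `roi_series`.
#' @return `actin_kinetics` list: `times_min`, `ratio_is_cell`,
#'   `ratio_cis_is`, `frame_interval`.
#' @export
actin_ratio_series <- function(series) {
  bad <- series$cell_fi <= 0 | series$is_fi <= 0
  if (any(bad))
    sp_warn("zero_denominator",
            sprintf("%d frame(s) with zero mean FI excluded", sum(bad)))
  r1 <- ifelse(series$cell_fi > 0, series$is_fi / series$cell_fi, NA_real_)
  r2 <- ifelse(series$is_fi > 0, series$cis_fi / series$is_fi, NA_real_)
  r1[bad] <- NA_real_; r2[bad] <- NA_real_
  dt <- if (length(series$times_min) > 1) diff(series$times_min)[1] else 1
  structure(list(times_min = series$times_min, ratio_is_cell = r1,
                 ratio_cis_is = r2, frame_interval = dt),
            class = "actin_kinetics")
}

## longest contiguous run of TRUE; returns c(start, length) (0 0 if none)
longest_run <- function(flags) {
  flags[is.na(flags)] <- FALSE
  r <- rle(flags)
  if (!any(r$values)) return(c(0L, 0L))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  k <- true_runs[which.max(r$lengths[true_runs])]
  c(starts[k], r$lengths[k])
}

#' Duration and magnitude of cortical actin reorganization at the IS
#'
#' The reorganization interval is the longest contiguous run of frames with
#' `ratio_is_cell` strictly above `1 + delta`; its length times the frame
#' interval is the duration. The tolerance `delta` (default 0.05) guards the
#' bare ">1" rule against noise-driven run fragmentation.
#'
#' @param kinetics an `actin_kinetics`.
#' @param delta tolerance around ratio 1.
#' @return list: `duration` (minutes), `peak_time` (minutes), `max_ratio`.
#'   An all-below series returns duration 0 with the global maximum.
#' @export
reorganization_interval <- function(kinetics, delta = 0.05) {
  r <- kinetics$ratio_is_cell
  run <- longest_run(r > 1 + delta)
  dt <- kinetics$frame_interval
  if (run[2] == 0L) {
    i <- which.max(r)
    return(list(duration = 0, peak_time = kinetics$times_min[i],
                max_ratio = max(r, na.rm = TRUE)))
  }
  idx <- run[1]:(run[1] + run[2] - 1L)
  i <- idx[which.max(r[idx])]
  list(duration = run[2] * dt, peak_time = kinetics$times_min[i],
       max_ratio = r[i])
}

#' Duration of transient actin depletion at the central synapse
#'
#' Longest contiguous run of frames with `ratio_cis_is` below `1 - delta`.
#'
#' @inheritParams reorganization_interval
#' @return list: `depletion_present`, `depletion_duration` (minutes).
#' @export
depletion_interval <- function(kinetics, delta = 0.05) {
  run <- longest_run(kinetics$ratio_cis_is < 1 - delta)
  dur <- run[2] * kinetics$frame_interval
  list(depletion_present = dur > 0, depletion_duration = dur)
}

#' Sensor fluorescence-intensity ratio relative to a baseline time point
#'
#' `ratio[t] = FI[t] / FI[baseline]`, the normalization used for
#' DAG-sensor kinetics (baseline conventionally at t = 30 min).
#'
#' @param fi mean cell-ROI FI per frame.
#' @param times_min frame times, minutes.
#' @param baseline_time baseline time point, minutes.
#' @return numeric ratio series.
#' @export
sensor_fi_ratio <- function(fi, times_min, baseline_time = 30) {
  if (length(fi) != length(times_min))
    sp_stop("invalid_series", "fi and times differ in length")
  i <- which.min(abs(times_min - baseline_time))
  dt <- if (length(times_min) > 1) min(diff(times_min)) else Inf
  if (abs(times_min[i] - baseline_time) > dt / 2 + 1e-9)
    sp_stop("invalid_series",
            sprintf("no frame at baseline time %g min", baseline_time))
  if (fi[i] <= 0) sp_stop("zero_baseline", "baseline FI is zero")
  fi / fi[i]
}

#' Residence half-life of a membrane-recruited reporter at the synapse
#'
#' Time from the FI peak until the signal first falls to half of the
#' peak-over-baseline amplitude (baseline = final value), linearly
#' interpolated between frames. If the signal never falls that far, the
#' observation span after the peak is returned with `censored = TRUE`.
#'
#' @param fi FI series.
#' @param times_min frame times, minutes.
#' @return list: `half_life` (minutes), `censored`, `peak_time`.
#' @export
residence_half_life <- function(fi, times_min) {
  if (length(fi) < 3) sp_stop("invalid_series", "need >= 3 frames")
  p <- which.max(fi)
  baseline <- fi[length(fi)]
  target <- baseline + 0.5 * (fi[p] - baseline)
  if (p == length(fi) || fi[p] <= baseline)
    return(list(half_life = times_min[length(fi)] - times_min[p],
                censored = TRUE, peak_time = times_min[p]))
  for (j in (p + 1):length(fi)) {
    if (fi[j] <= target) {
      frac <- (fi[j - 1] - target) / (fi[j - 1] - fi[j])
      t_cross <- times_min[j - 1] + frac * (times_min[j] - times_min[j - 1])
      return(list(half_life = t_cross - times_min[p], censored = FALSE,
                  peak_time = times_min[p]))
    }
  }
  list(half_life = times_min[length(fi)] - times_min[p], censored = TRUE,
       peak_time = times_min[p])
}
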