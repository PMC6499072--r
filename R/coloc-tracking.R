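#' Fluorogram (Pearson) colocalization within a mask
#'
#' Standard Pearson product-moment correlation over the paired pixel
#' intensities of two channels, restricted to a mask — the scatter-plot
#' ("fluorogram") colocalization statistic.
#'
#' @param ch1,ch2 intensity rasters (or vectors) of identical shape.
#' @param mask optional logical raster selecting the pixels to pair; all
#'   pixels by default.
#' @return `fluorogram` list: `pearson_r`, `n_pixels`, and the paired
#'   intensities `pairs` (two-column matrix, for scatter export).
#' @export
pearson_colocalization <- function(ch1, ch2, mask = NULL) {
  if (!identical(dim(ch1), dim(ch2)) || length(ch1) != length(ch2))
    sp_stop("invalid_scene", "channels differ in shape")
  if (is.null(mask)) mask <- rep(TRUE, length(ch1))
  v1 <- as.numeric(ch1)[as.logical(mask)]
  v2 <- as.numeric(ch2)[as.logical(mask)]
  if (length(v1) < 2) sp_stop("invalid_scene", "mask selects < 2 pixels")
  if (sd(v1) == 0 || sd(v2) == 0)
    sp_stop("undefined_correlation", "zero variance in a channel")
  structure(list(pearson_r = cor(v1, v2), n_pixels = length(v1),
                 pairs = cbind(intensity1 = v1, intensity2 = v2)),
            class = "fluorogram")
}

#' Link per-frame spot detections into tracks
#'
#' Greedy mutual-nearest-neighbor linking: between consecutive frames,
#' candidate pairs are taken in order of increasing distance and a link is
#' made only when the two spots are each other's nearest neighbors and the
#' displacement does not exceed `max_link_px`. A jump beyond `max_link_px`
#' terminates the track and starts a new one. Deterministic by construction.
#'
#' @param detections data frame with columns `frame`, `y`, `x` (0-based
#'   pixel coordinates), or a list of per-frame coordinate matrices.
#' @param max_link_px maximum per-frame displacement, pixels.
#' @param min_track_len minimum track length, frames; shorter tracks are
#'   discarded.
#' @return list of `track` objects (data frames `frame`, `y`, `x`).
#' @export
link_tracks <- function(detections, max_link_px, min_track_len = 2L) {
  if (is.list(detections) && !is.data.frame(detections)) {
    detections <- do.call(rbind, lapply(seq_along(detections), function(t) {
      m <- rbind(detections[[t]])
      if (is.null(m) || nrow(m) == 0) return(NULL)
      data.frame(frame = t, y = m[, 1], x = m[, 2])
    }))
  }
  frames <- sort(unique(detections$frame))
  if (length(frames) < 2) sp_stop("invalid_series", "need >= 2 frames")
  by_frame <- split(detections, detections$frame)
  ## active tracks: list of data frames; `open` maps detection row in the
  ## previous frame to a track id
  tracks <- list()
  prev <- by_frame[[as.character(frames[1])]]
  prev_track <- integer(nrow(prev))
  for (i in seq_len(nrow(prev))) {
    tracks[[length(tracks) + 1L]] <- prev[i, , drop = FALSE]
    prev_track[i] <- length(tracks)
  }
  for (fi in seq_along(frames)[-1]) {
    cur <- by_frame[[as.character(frames[fi])]]
    cur_track <- integer(if (is.null(cur)) 0L else nrow(cur))
    if (!is.null(cur) && nrow(cur) > 0 && nrow(prev) > 0) {
      dy <- outer(prev$y, cur$y, "-")
      dx <- outer(prev$x, cur$x, "-")
      dmat <- sqrt(dy^2 + dx^2)
      used_p <- logical(nrow(prev)); used_c <- logical(nrow(cur))
      ord <- order(dmat)
      for (o in ord) {
        if (dmat[o] > max_link_px) break
        p <- (o - 1L) %% nrow(prev) + 1L
        cc <- (o - 1L) %/% nrow(prev) + 1L
        if (used_p[p] || used_c[cc]) next
        ## mutual nearest among unused
        if (which.min(ifelse(used_c, Inf, dmat[p, ])) != cc) next
        if (which.min(ifelse(used_p, Inf, dmat[, cc])) != p) next
        used_p[p] <- TRUE; used_c[cc] <- TRUE
        tid <- prev_track[p]
        tracks[[tid]] <- rbind(tracks[[tid]], cur[cc, , drop = FALSE])
        cur_track[cc] <- tid
      }
    }
    if (!is.null(cur)) {
      for (i in seq_len(nrow(cur))) {
        if (cur_track[i] == 0L) {
          tracks[[length(tracks) + 1L]] <- cur[i, , drop = FALSE]
          cur_track[i] <- length(tracks)
        }
      }
      prev <- cur
      prev_track <- cur_track
    } else {
      prev <- cur[0, ]
      prev_track <- integer(0)
    }
  }
  tracks <- lapply(tracks, function(tr) {
    rownames(tr) <- NULL
    structure(tr, class = c("track", "data.frame"))
  })
  Filter(function(tr) nrow(tr) >= min_track_len, tracks)
}

#' Mean speed of a track
#'
#' Mean over steps of the step displacement converted to micrometers per
#' second.
#'
#' @param track a `track` data frame (`frame`, `y`, `x` in pixels).
#' @param pixel_size micrometers per pixel.
#' @param frame_interval_s seconds between consecutive frames.
#' @return mean speed, micrometers per second.
#' @export
mean_speed <- function(track, pixel_size, frame_interval_s) {
  if (nrow(track) < 2) sp_stop("track_too_short", "track has < 2 points")
  d_px <- sqrt(diff(track$y)^2 + diff(track$x)^2)
  dt_s <- diff(track$frame) * frame_interval_s
  mean(d_px * pixel_size / dt_s)
}

#' Per-track and pooled speed summaries for a set of tracks
#' @param tracks list of `track` objects.
#' @inheritParams mean_speed
#' @return data frame: `track_id`, `n_points`, `mean_speed_um_s`; pooled
#'   mean in attribute `pooled_mean`.
#' @export
track_speeds <- function(tracks, pixel_size, frame_interval_s) {
  if (length(tracks) == 0L) sp_stop("empty_cohort", "no tracks")
  sp <- vapply(tracks, mean_speed, numeric(1), pixel_size, frame_interval_s)
  out <- data.frame(track_id = seq_along(tracks),
                    n_points = vapply(tracks, nrow, integer(1)),
                    mean_speed_um_s = sp)
  ## per-vesicle mean and step-pooled mean can differ; report both
  all_steps <- unlist(lapply(tracks, function(tr)
    sqrt(diff(tr$y)^2 + diff(tr$x)^2) * pixel_size /
      (diff(tr$frame) * frame_interval_s)))
  attr(out, "pooled_mean") <- mean(all_steps)
  out
}
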