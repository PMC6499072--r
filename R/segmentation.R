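## Conjugate segmentation: APC and T-cell masks by Otsu thresholding +
## largest connected component, contact (IS) segment by boundary adjacency.

#' Segmentation configuration
#' @param t_cell_channel channel role used to segment the T cell
#'   (`"actin"` or `"organelle"`).
#' @param contact_radius adjacency radius (pixels) between the T-cell
#'   boundary and the APC for the contact segment.
#' @return list of settings for [segment_conjugate()].
#' @export
segmentation_config <- function(t_cell_channel = "actin",
                                contact_radius = 1) {
  list(t_cell_channel = t_cell_channel, contact_radius = contact_radius)
}

#' Segment a T cell/APC conjugate in one 2D frame
#'
#' The APC is the largest connected component above the Otsu threshold of
#' the APC-dye channel; the T cell is the largest component above the Otsu
#' threshold of the T-cell channel that does not overlap the APC; the
#' contact (IS) segment is the set of T-cell boundary pixels within a
#' 1-pixel dilation of the APC. Centroids are intensity-unweighted over the
#' binary masks; the IS centroid is the centroid of the contact segment and
#' the IS axis is the unit vector from the cell centroid toward it.
#'
#' @param scene an [image_scene].
#' @param t,z frame/slice indices.
#' @param config a [segmentation_config()].
#' @return `conjugate_geometry` list: `t_cell_mask`, `apc_mask`,
#'   `contact_segment` (0-based (y, x), ordered by y), `cell_centroid`,
#'   `is_centroid`, `is_axis`, `B` (pixels).
#' @export
segment_conjugate <- function(scene, t = 1L, z = 1L,
                              config = segmentation_config()) {
  apc_img <- scene_frame(scene, "apc_dye", t, z)
  thr_a <- otsu_threshold(apc_img)
  apc_fg <- apc_img > thr_a
  if (!any(apc_fg) || diff(range(apc_img)) == 0)
    sp_stop("no_conjugate", "no APC signal above threshold")
  apc_mask <- fill_holes(largest_component(apc_fg))

  tc_img <- scene_frame(scene, config$t_cell_channel, t, z)
  ## the T-cell channel is tri-modal (background, cytosol, bright cortical
  ## band); 2-class Otsu can latch onto the cytosol/band split during a
  ## cortical burst. Use the 3-class decomposition and threshold halfway
  ## between the background and cytosol class means.
  th3 <- otsu_thresholds3(tc_img)
  lo_mean <- mean(tc_img[tc_img <= th3[1]])
  mid_vals <- tc_img[tc_img > th3[1] & tc_img <= th3[2]]
  mid_mean <- if (length(mid_vals) > 0) mean(mid_vals) else th3[2]
  thr_t <- (lo_mean + mid_mean) / 2
  tc_fg <- tc_img > thr_t
  lab <- label_components(tc_fg)
  if (max(lab) == 0L) sp_stop("no_cell", "no T-cell signal above threshold")
  ## largest component with no more than half its area on the APC
  sizes <- tabulate(lab[lab > 0L])
  overlap <- vapply(seq_along(sizes), function(k)
    sum(lab == k & apc_mask), numeric(1))
  candidates <- which(overlap < sizes / 2)
  if (length(candidates) == 0L)
    sp_stop("no_cell", "no T-cell component distinct from the APC")
  k <- candidates[which.max(sizes[candidates])]
  ## the cortical ring may threshold hollow: fill before measuring shape
  t_cell_mask <- fill_holes(matrix(lab == k, nrow(lab), ncol(lab))) & !apc_mask
  runners_up <- setdiff(candidates, k)
  if (length(runners_up) > 0L && max(sizes[runners_up]) >= sizes[k] / 2)
    sp_warn("multiple_conjugates",
            "multiple T-cell candidates; analyzing the largest only")

  contact <- mask_boundary(t_cell_mask) &
    binary_dilate(apc_mask, config$contact_radius)
  if (!any(contact)) sp_stop("no_conjugate", "empty contact segment")
  cc <- mask_coords(contact)
  cc <- cc[order(cc[, 1], cc[, 2]), , drop = FALSE]
  cell_c <- mask_centroid(t_cell_mask)
  is_c <- weighted_centroid(cc)
  structure(list(
    t_cell_mask = t_cell_mask, apc_mask = apc_mask, contact_segment = cc,
    cell_centroid = cell_c, is_centroid = is_c,
    is_axis = unit_vector(is_c - cell_c),
    B = sqrt(sum((is_c - cell_c)^2))
  ), class = "conjugate_geometry")
}

#' Organelle-detection configuration
#' @param dog_sigma inner difference-of-Gaussians scale, pixels.
#' @param k_mad robust threshold: median + `k_mad` * MAD of the band-pass
#'   response inside the cell.
#' @param min_size minimum punctum area, pixels.
#' @return settings list for [detect_organelles()].
#' @export
detection_config <- function(dog_sigma = 1.5, k_mad = 5, min_size = 4L) {
  list(dog_sigma = dog_sigma, k_mad = k_mad, min_size = min_size)
}

#' Detect organelle puncta inside the T cell
#'
#' Puncta are connected components of the difference-of-Gaussians band-pass
#' response above a robust threshold (median + k * MAD over the cell mask),
#' restricted to the T-cell mask and size-filtered. The overall organelle
#' center of mass (MVB centroid) is the intensity-weighted centroid of all
#' punctum pixels.
#'
#' @param scene an [image_scene].
#' @param geometry a `conjugate_geometry`.
#' @param t,z frame/slice indices.
#' @param config a [detection_config()].
#' @return `organelle_detection` list: `labels` raster, `puncta` data frame
#'   (label, y, x, area, intensity; 0-based subpixel centroids), `centroid`
#'   (intensity-weighted, 0-based pixels).
#' @export
detect_organelles <- function(scene, geometry, t = 1L, z = 1L,
                              config = detection_config()) {
  img <- scene_frame(scene, "organelle", t, z)
  resp <- dog_filter(img, config$dog_sigma)
  inside <- resp[geometry$t_cell_mask]
  thr <- median(inside) + config$k_mad * mad(inside)
  fg <- resp > thr & geometry$t_cell_mask
  lab <- label_components(fg)
  if (max(lab) == 0L) sp_stop("no_organelles", "no puncta above threshold")
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= config$min_size)
  if (length(keep) == 0L)
    sp_stop("no_organelles",
            sprintf("all puncta smaller than %d px", config$min_size))
  rows <- lapply(seq_along(keep), function(i) {
    k <- keep[i]
    coords <- mask_coords(matrix(lab == k, nrow(lab), ncol(lab)))
    w <- img[cbind(coords[, 1] + 1, coords[, 2] + 1)]
    cen <- weighted_centroid(coords, w)
    data.frame(label = i, y = cen[1], x = cen[2],
               area = nrow(coords), intensity = sum(w))
  })
  puncta <- do.call(rbind, rows)
  all_mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  coords <- mask_coords(all_mask)
  w <- img[cbind(coords[, 1] + 1, coords[, 2] + 1)]
  labels <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) labels[lab == keep[i]] <- i
  structure(list(labels = labels, puncta = puncta,
                 centroid = weighted_centroid(coords, w)),
            class = "organelle_detection")
}

#' Detect the MTOC as the brightest compact blob in the T cell
#'
#' The candidate blobs are connected components above the Otsu threshold of
#' the MTOC channel inside the T-cell mask; the blob with the largest
#' integrated intensity wins (ties broken by lowest (y, x) of the blob's
#' first pixel in raster order). Position is the intensity-weighted centroid.
#'
#' @inheritParams detect_organelles
#' @return `organelle_detection` with a single-row `puncta` table and
#'   `centroid` = MTOC position (0-based pixels).
#' @export
detect_mtoc <- function(scene, geometry, t = 1L, z = 1L) {
  img <- scene_frame(scene, "mtoc", t, z)
  vals <- img[geometry$t_cell_mask]
  if (diff(range(vals)) == 0) sp_stop("no_mtoc", "flat MTOC channel")
  thr <- otsu_threshold(vals)
  fg <- img > thr & geometry$t_cell_mask
  lab <- label_components(fg)
  if (max(lab) == 0L) sp_stop("no_mtoc", "no blob above threshold")
  totals <- vapply(seq_len(max(lab)), function(k)
    sum(img[lab == k]), numeric(1))
  best <- which(totals == max(totals))
  if (length(best) > 1L) {
    ## deterministic tie-break: blob whose first pixel comes first in
    ## raster (y, x) order
    first_px <- vapply(best, function(k) which(t(lab) == k)[1], numeric(1))
    best <- best[which.min(first_px)]
  }
  coords <- mask_coords(matrix(lab == best, nrow(lab), ncol(lab)))
  w <- img[cbind(coords[, 1] + 1, coords[, 2] + 1)]
  cen <- weighted_centroid(coords, w)
  structure(list(
    labels = matrix(as.integer(lab == best), nrow(lab), ncol(lab)),
    puncta = data.frame(label = 1L, y = cen[1], x = cen[2],
                        area = nrow(coords), intensity = sum(w)),
    centroid = cen), class = "organelle_detection")
}
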