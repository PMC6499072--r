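#' Organelle polarization index (A/B)
#'
#' The polarization index is the signed ratio A/B: A is the scalar
#' projection of the organelle center-of-mass displacement (from the cell
#' center of mass) onto the axis running from the cell center toward the IS
#' centroid — negative when the organelle sits on the side opposite the
#' synapse — and B is the distance from the cell center to the IS centroid.
#' Division by B normalizes for cell size and shape, and the ratio is
#' bounded to \[-1, +1\]. Conjugates with index strictly above the cutoff
#' (default 0.25) are scored as polarized.
#'
#' @param geometry a `conjugate_geometry` (from [segment_conjugate()] or a
#'   generator sidecar): needs `cell_centroid`, `is_centroid` and, for the
#'   default axis, `is_axis`.
#' @param organelle_centroid organelle center of mass, same coordinate frame
#'   and units as the geometry (pixels or micrometers — the index is
#'   scale-invariant).
#' @param organelle `"MVB"` or `"MTOC"` (label only).
#' @param cutoff polarization cutoff; strictly greater scores as polarized.
#' @param axis `"is_centroid"` (default) projects onto the axis through the
#'   IS centroid; `"nearest_contact"` uses the axis through the contact pixel
#'   nearest to the cell centroid (variant, requires `contact_segment`).
#' @return `polarization_result` list: `A`, `B`, `pol_index` (clamped),
#'   `raw_ratio`, `polarized`, `organelle`, `cutoff_used`.
#' @export
polarization_index <- function(geometry, organelle_centroid,
                               organelle = c("MVB", "MTOC"),
                               cutoff = 0.25,
                               axis = c("is_centroid", "nearest_contact")) {
  organelle <- match.arg(organelle)
  axis <- match.arg(axis)
  cell_c <- as.numeric(geometry$cell_centroid)
  is_c <- as.numeric(geometry$is_centroid)
  if (axis == "nearest_contact") {
    cs <- rbind(geometry$contact_segment)
    d2 <- rowSums((sweep(cs, 2, cell_c))^2)
    is_c <- as.numeric(cs[which.min(d2), ])
  }
  diff_b <- is_c - cell_c
  B <- sqrt(sum(diff_b^2))
  if (B <= 0) sp_stop("degenerate_geometry",
                      "cell centroid coincides with the IS centroid (B = 0)")
  u <- diff_b / B
  A <- sum((as.numeric(organelle_centroid) - cell_c) * u)
  raw <- A / B
  pol <- clamp(raw, -1, 1)
  structure(list(A = A, B = B, pol_index = pol, raw_ratio = raw,
                 polarized = pol > cutoff, organelle = organelle,
                 cutoff_used = cutoff),
            class = "polarization_result")
}

#' Percent of polarized synapses in a cohort
#'
#' @param results list of `polarization_result` objects sharing one cutoff.
#' @return percentage (0-100) of results with `polarized == TRUE`.
#' @export
cohort_polarization <- function(results) {
  if (length(results) == 0L) sp_stop("empty_cohort", "no results")
  cutoffs <- vapply(results, `[[`, numeric(1), "cutoff_used")
  if (length(unique(cutoffs)) > 1L)
    sp_stop("mixed_cutoffs", "results use different cutoffs")
  flags <- vapply(results, `[[`, logical(1), "polarized")
  100 * sum(flags) / length(flags)
}

#' Pearson correlation between paired MVB and MTOC polarization indexes
#'
#' @param mvb,mtoc numeric vectors of equal length (>= 3 pairs).
#' @return Pearson product-moment correlation coefficient.
#' @export
mvb_mtoc_correlation <- function(mvb, mtoc) {
  if (length(mvb) != length(mtoc) || length(mvb) < 3L)
    sp_stop("invalid_pairs", "need >= 3 paired indexes of equal length")
  if (sd(mvb) == 0 || sd(mtoc) == 0)
    sp_stop("undefined_correlation", "zero variance in one organelle's indexes")
  cor(mvb, mtoc)
}
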