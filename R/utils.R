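#' @useDynLib synapsepol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif median mad cor sd quantile
#' @importFrom utils write.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Signal a classed measurement error
#'
#' All recoverable failure modes in the pipeline (no cell detected, empty
#' cohort, degenerate geometry, ...) are signalled as classed conditions so
#' callers can field them per scene without string matching.
#'
#' @param class condition class, e.g. `"no_conjugate"`.
#' @param message human-readable description.
#' @keywords internal
sp_stop <- function(class, message) {
  stop(structure(
    class = c(class, "synapsepol_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

sp_warn <- function(class, message) {
  warning(structure(
    class = c(class, "synapsepol_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

## Coordinates are 0-based (y, x) with pixel centers at integers throughout
## the public interface; conversion to R's 1-based matrix indices happens at
## the last moment inside each function.

#' Pixel coordinates of a mask
#'
#' @param mask logical matrix `[ny, nx]`.
#' @return two-column matrix of 0-based (y, x) coordinates.
#' @keywords internal
mask_coords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  cbind(y = w[, 1] - 1, x = w[, 2] - 1)
}

#' Intensity-weighted centroid
#'
#' Computes sum(w * p) / sum(w) over pixel coordinates `p`. With `weights`
#' omitted all pixels weigh 1 (binary center of mass).
#'
#' @param coords two-column matrix of 0-based (y, x) coordinates.
#' @param weights optional nonnegative weights, one per row.
#' @return numeric (y, x) centroid, 0-based pixels.
#' @export
weighted_centroid <- function(coords, weights = NULL) {
  coords <- rbind(coords)
  if (nrow(coords) == 0L) sp_stop("empty_region", "no pixels to average")
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  if (any(weights < 0)) sp_stop("invalid_weights", "negative weights")
  s <- sum(weights)
  if (s <= 0) sp_stop("invalid_weights", "weights sum to zero")
  c(y = sum(weights * coords[, 1]) / s, x = sum(weights * coords[, 2]) / s)
}

mask_centroid <- function(mask) weighted_centroid(mask_coords(mask))

#' Minimum distance from each query pixel to a pixel set
#' @param query,set two-column (y, x) coordinate matrices (same units).
#' @return numeric vector, one distance per query row.
#' @keywords internal
dist_to_set <- function(query, set) {
  query <- rbind(query); set <- rbind(set)
  ## chunked to bound memory at ~1e6 doubles per block
  nq <- nrow(query)
  out <- numeric(nq)
  block <- max(1L, floor(1e6 / max(1L, nrow(set))))
  for (i0 in seq(1L, nq, by = block)) {
    i1 <- min(nq, i0 + block - 1L)
    dy <- outer(query[i0:i1, 1], set[, 1], "-")
    dx <- outer(query[i0:i1, 2], set[, 2], "-")
    out[i0:i1] <- sqrt(apply(dy * dy + dx * dx, 1, min))
  }
  out
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) sp_stop("degenerate_geometry", "zero-length axis vector")
  v / n
}

## FNV-1a over a string; used for the run-manifest config fingerprint so the
## package needs no hashing dependency.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
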