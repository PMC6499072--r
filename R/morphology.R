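## Raster primitives: thresholding, labelling, binary morphology, filtering.
## 2D masks are [ny, nx] logical matrices; 3D masks are [nz, ny, nx] arrays.

#' Otsu threshold of an intensity image
#'
#' Maximizes between-class variance on a 256-bin histogram spanning the data
#' range, so the returned threshold is equivariant under affine intensity
#' rescaling (segmentation is invariant to uniform gain).
#'
#' @param x numeric vector/matrix/array of intensities.
#' @param n_bins histogram resolution.
#' @return scalar threshold; pixels `> threshold` are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  mids[which.max(sigma_b)]
}

#' Multi-level (3-class) Otsu thresholds
#'
#' Maximizes three-class between-class variance over all threshold pairs on
#' a 256-bin histogram. For tri-modal fluorescence frames (background,
#' cytosol, bright cortical band) the lower threshold separates background
#' from cell reliably even when the upper two modes dominate the variance.
#'
#' @param x numeric vector/matrix of intensities.
#' @param n_bins histogram resolution.
#' @return numeric vector `c(lower, upper)` of thresholds.
#' @export
otsu_thresholds3 <- function(x, n_bins = 128L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(c(rng[1], rng[1]))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  W <- c(0, cumsum(p))
  M <- c(0, cumsum(p * mids))
  ## class statistic between bin indices (a, b]: sum over bins a+1..b
  best <- -Inf; best_ij <- c(1L, 2L)
  for (i in seq_len(n_bins - 2L)) {
    w0 <- W[i + 1]; m0 <- M[i + 1]
    if (w0 <= 0) next
    js <- (i + 1L):(n_bins - 1L)
    w1 <- W[js + 1] - w0
    m1 <- M[js + 1] - m0
    w2 <- 1 - W[js + 1]
    m2 <- M[n_bins + 1] - M[js + 1]
    ok <- w1 > 0 & w2 > 0
    if (!any(ok)) next
    s <- rep(-Inf, length(js))
    s[ok] <- m0^2 / w0 + m1[ok]^2 / w1[ok] + m2[ok]^2 / w2[ok]
    j_best <- which.max(s)
    if (s[j_best] > best) {
      best <- s[j_best]
      best_ij <- c(i, js[j_best])
    }
  }
  c(mids[best_ij[1]], mids[best_ij[2]])
}

#' Label connected components of a binary mask
#'
#' 8-connectivity in 2D, 26-connectivity in 3D by default. Labels are
#' assigned in deterministic raster order.
#'
#' @param mask logical matrix or 3D array.
#' @param full use full (8/26) connectivity; `FALSE` gives 4/6.
#' @return integer raster of labels, 0 = background.
#' @export
label_components <- function(mask, full = TRUE) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    sp_stop("invalid_mask", "mask must be a 2D matrix or 3D array")
  two_d <- length(d) == 2L
  if (two_d) {
    arr <- array(mask, dim = c(1L, d))
  } else {
    arr <- mask
  }
  lab <- label_components_cpp(as.logical(arr), as.integer(dim(arr)), full)
  lab <- array(lab, dim = dim(arr))
  if (two_d) lab <- array(lab[1L, , ], dim = d)
  lab
}

#' Keep the largest connected component
#' @param mask logical matrix/array.
#' @return logical raster of the same shape; all-`FALSE` if the mask is empty.
#' @export
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(array(FALSE, dim = dim(mask)))
  sizes <- tabulate(lab[lab > 0L])
  array(lab == which.max(sizes), dim = dim(mask))
}

disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

shift_mask <- function(mask, dy, dx) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(FALSE, ny, nx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  if (length(ys) == 0 || length(xs) == 0) return(out)
  out[ys, xs] <- mask[ys - dy, xs - dx]
  out
}

#' Binary dilation / erosion / closing with a disc structuring element
#' @param mask logical matrix.
#' @param radius disc radius in pixels.
#' @name morphology
#' @export
binary_dilate <- function(mask, radius = 1) {
  off <- disc_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift_mask(mask, off$dy[i], off$dx[i])
  out
}

#' @rdname morphology
#' @export
binary_erode <- function(mask, radius = 1) {
  !binary_dilate(!mask, radius)
}

#' @rdname morphology
#' @export
binary_closing <- function(mask, radius = 2) {
  binary_erode(binary_dilate(mask, radius), radius)
}

#' Fill holes: background regions not connected to the raster border
#' @param mask logical matrix.
#' @export
fill_holes <- function(mask) {
  lab <- label_components(!mask, full = FALSE)
  border_labels <- setdiff(unique(c(lab[1, ], lab[nrow(lab), ],
                                    lab[, 1], lab[, ncol(lab)])), 0L)
  holes <- lab > 0L & !(lab %in% border_labels)
  mask | matrix(holes, nrow(mask), ncol(mask))
}

#' Boundary pixels of a mask (8-connected outer edge)
#' @param mask logical matrix.
#' @return logical matrix marking mask pixels adjacent to background or to
#'   the raster border.
#' @export
mask_boundary <- function(mask) {
  interior <- mask
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    padded <- shift_mask(mask, dy, dx)
    ## pixels shifted in from outside the raster count as background
    interior <- interior & padded
  }
  ## raster-border mask pixels are boundary by construction
  edge <- matrix(FALSE, nrow(mask), ncol(mask))
  edge[c(1, nrow(mask)), ] <- TRUE
  edge[, c(1, ncol(mask))] <- TRUE
  mask & (!interior | edge)
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

convolve_1d_replicate <- function(m, k, along) {
  ## along = 1: convolve down columns; along = 2: across rows
  r <- (length(k) - 1L) / 2L
  if (r == 0) return(m)
  if (along == 2L) return(t(convolve_1d_replicate(t(m), k, 1L)))
  n <- nrow(m)
  pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
               m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * pad[(i - 1L) + seq_len(n), , drop = FALSE]
  out
}

#' Separable Gaussian blur of a 2D image
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; 0 returns the input.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  convolve_1d_replicate(convolve_1d_replicate(img, k, 1L), k, 2L)
}

#' Difference-of-Gaussians band-pass response
#' @param img numeric matrix.
#' @param sigma1 inner scale (pixels); `sigma2` defaults to `1.6 * sigma1`.
#' @param sigma2 outer scale.
#' @export
dog_filter <- function(img, sigma1, sigma2 = 1.6 * sigma1) {
  gaussian_blur(img, sigma1) - gaussian_blur(img, sigma2)
}
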