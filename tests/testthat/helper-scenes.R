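## Shared fixtures, built in code and memoized for the session so expensive
## scenes render once.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

## default static conjugate with moderate polarization
static_scene <- function() fixture("static_scene", function()
  generate_conjugate_scene(scene_spec(seed = 42, true_pol_index = 0.5)))

## noise-free, nearly blur-free static conjugate
clean_scene <- function() fixture("clean_scene", function()
  generate_conjugate_scene(scene_spec(seed = 42, true_pol_index = 0.5,
                                      psf_sigma = 0.1, poisson_scale = 0,
                                      gaussian_sd = 0)))

## hand-built scene: disc-shaped cell and APC with Gaussian spots at known
## positions — lets tests own the ground truth without the generator
manual_spot_scene <- function(spot_yx, spot_amp = NULL, shape = c(96, 96),
                              spot_sigma = 1.5) {
  ny <- shape[1]; nx <- shape[2]
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  cell <- (yy - (ny - 1) / 2)^2 + (xx - nx * 0.35)^2 <= (nx * 0.28)^2
  apc <- (yy - (ny - 1) / 2)^2 + (xx - nx * 0.78)^2 <= (nx * 0.2)^2 & !cell
  org <- matrix(0.01, ny, nx)
  if (!is.null(spot_yx)) {
    spot_yx <- rbind(spot_yx)
    if (is.null(spot_amp)) spot_amp <- rep(1, nrow(spot_yx))
    for (i in seq_len(nrow(spot_yx))) {
      g <- outer(exp(-(0:(ny - 1) - spot_yx[i, 1])^2 / (2 * spot_sigma^2)),
                 exp(-(0:(nx - 1) - spot_yx[i, 2])^2 / (2 * spot_sigma^2)))
      org <- org + spot_amp[i] * g
    }
  }
  data <- array(0, dim = c(1, 1, 4, ny, nx))
  data[1, 1, 1, , ] <- 0.02 + 0.8 * apc
  data[1, 1, 2, , ] <- 0.02 + 0.5 * cell
  data[1, 1, 3, , ] <- org
  data[1, 1, 4, , ] <- org
  scene <- image_scene(data, c(apc_dye = 1, actin = 2, organelle = 3,
                               mtoc = 4), pixel_size = 0.2)
  list(scene = scene, cell_mask = cell, apc_mask = apc)
}

## geometry stub for polarization tests: everything in one coordinate frame
geom_stub <- function(cell_centroid, is_centroid, contact = NULL) {
  structure(list(cell_centroid = cell_centroid, is_centroid = is_centroid,
                 contact_segment = contact),
            class = "conjugate_geometry")
}

## polarization_result with a prescribed index (unit geometry)
pol_result_with_index <- function(idx, cutoff = 0.25) {
  polarization_index(geom_stub(c(0, 0), c(0, 1)), c(0, idx), cutoff = cutoff)
}

## random flattened-disc conjugate geometry sampled on a pixel grid; returns
## the geometry pieces plus the cell-mask pixel coordinates (for organelle
## placement). Brute-force construction independent of the generator.
random_flat_geometry <- function(n_grid = 48) {
  r <- runif(1, 8, 16)
  cx_plane <- n_grid * 0.6
  cy <- n_grid / 2 + runif(1, -3, 3)
  flat <- runif(1, 0.4, 0.9)
  cx <- cx_plane - flat * r
  yy <- matrix(0:(n_grid - 1), n_grid, n_grid)
  xx <- matrix(0:(n_grid - 1), n_grid, n_grid, byrow = TRUE)
  mask <- (yy - cy)^2 + (xx - cx)^2 <= r^2 & xx < cx_plane
  coords <- which(mask, arr.ind = TRUE) - 1
  facet <- coords[coords[, 2] == max(coords[, 2]), , drop = FALSE]
  list(geometry = geom_stub(colMeans(coords)[c(1, 2)],
                            colMeans(facet)[c(1, 2)]),
       cell_coords = coords)
}
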