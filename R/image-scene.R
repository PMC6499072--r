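#' Multi-channel image scene container
#'
#' Holds a calibrated intensity raster with axes (t, z, channel, y, x) — any
#' axis may be singleton — together with the mapping from channel roles
#' (`apc_dye`, `actin`, `organelle`, `mtoc`, `sensor`) to channel indices and
#' the physical calibration.
#'
#' @param data numeric array. Accepted shapes: `[y, x]`, `[c, y, x]`,
#'   `[z, c, y, x]`, or the full `[t, z, c, y, x]`; anything below 5D is
#'   promoted with singleton leading axes.
#' @param channel_roles named integer vector mapping role to channel index
#'   (1-based).
#' @param pixel_size lateral calibration, micrometers per pixel.
#' @param z_step axial step, micrometers.
#' @param frame_interval time between frames, minutes.
#' @return an object of class `image_scene`.
#' @export
image_scene <- function(data, channel_roles, pixel_size,
                        z_step = pixel_size, frame_interval = 1) {
  d <- dim(data)
  if (is.null(d)) sp_stop("invalid_scene", "data must be an array")
  if (length(d) < 2L || length(d) > 5L)
    sp_stop("invalid_scene", "data must have between 2 and 5 axes")
  while (length(dim(data)) < 5L)
    data <- array(data, dim = c(1L, dim(data)))
  if (any(data < 0, na.rm = TRUE))
    sp_stop("invalid_scene", "intensities must be nonnegative")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    sp_stop("invalid_scene", "pixel_size must be > 0")
  if (z_step <= 0) sp_stop("invalid_scene", "z_step must be > 0")
  if (frame_interval <= 0)
    sp_stop("invalid_scene", "frame_interval must be > 0")
  n_channels <- dim(data)[3]
  roles <- as.integer(channel_roles)
  names(roles) <- names(channel_roles)
  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    sp_stop("invalid_scene", "channel_roles must be named")
  if (any(roles < 1L | roles > n_channels))
    sp_stop("invalid_scene",
            sprintf("channel role index out of range 1..%d", n_channels))
  structure(
    list(data = data, channel_roles = roles, pixel_size = pixel_size,
         z_step = z_step, frame_interval = frame_interval),
    class = "image_scene"
  )
}

#' @export
print.image_scene <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_scene> t=%d z=%d c=%d y=%d x=%d  %.3g um/px, z step %.3g um, dt %.3g min\n",
    d[1], d[2], d[3], d[4], d[5], x$pixel_size, x$z_step, x$frame_interval))
  cat("channels:", paste(sprintf("%s=%d", names(x$channel_roles),
                                 x$channel_roles), collapse = ", "), "\n")
  invisible(x)
}

scene_dims <- function(scene) {
  d <- dim(scene$data)
  list(t = d[1], z = d[2], c = d[3], y = d[4], x = d[5])
}

channel_index <- function(scene, role) {
  if (!role %in% names(scene$channel_roles))
    sp_stop("missing_channel",
            sprintf("channel role '%s' not declared", role))
  scene$channel_roles[[role]]
}

#' Extract one 2D frame of a scene
#' @param scene an `image_scene`.
#' @param role channel role name.
#' @param t,z frame and slice indices (1-based).
#' @return numeric `[y, x]` matrix.
#' @export
scene_frame <- function(scene, role, t = 1L, z = 1L) {
  ci <- channel_index(scene, role)
  d <- dim(scene$data)
  matrix(scene$data[t, z, ci, , ], d[4], d[5])
}

#' Extract one channel's z-stack at a time point
#' @inheritParams scene_frame
#' @return numeric `[z, y, x]` array.
#' @export
scene_stack <- function(scene, role, t = 1L) {
  ci <- channel_index(scene, role)
  d <- dim(scene$data)
  array(scene$data[t, , ci, , ], dim = d[c(2, 4, 5)])
}

#' Pixel/micrometer conversions
#'
#' Exact inverses of one another (`um_to_px(px_to_um(x)) == x`).
#' @param x lengths to convert.
#' @param scene an `image_scene` (uses lateral calibration).
#' @name calibration
#' @export
px_to_um <- function(x, scene) x * scene$pixel_size

#' @rdname calibration
#' @export
um_to_px <- function(x, scene) x / scene$pixel_size
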