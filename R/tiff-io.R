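## Minimal baseline TIFF codec (little-endian, uncompressed, grayscale,
## multi-page; 32-bit float or 8/16-bit unsigned). No imaging package with
## TIFF support is available in the target environment, so the subset of the
## format the pipeline needs is implemented here. Pages are written in TZC
## order with the axis layout recorded in the ImageDescription tag.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, description = 270L, strip_offsets = 273L,
               samples = 277L, rows_per_strip = 278L, strip_bytes = 279L,
               sample_format = 339L)

#' Write a multi-page grayscale TIFF
#'
#' @param pages list of numeric matrices `[y, x]`, all of one shape.
#' @param path output file.
#' @param description string stored in the first page's ImageDescription
#'   (used for the axis layout, e.g. `"axes=TZCYX;t=3;z=1;c=4"`).
#' @param format `"float32"`, `"uint16"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(path, pages, description = NULL,
                       format = c("float32", "uint16", "uint8")) {
  format <- match.arg(format)
  if (is.matrix(pages)) pages <- list(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  bits <- switch(format, float32 = 32L, uint16 = 16L, uint8 = 8L)
  fmt_code <- if (format == "float32") 3L else 1L
  bytes_pp <- bits / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  w_int <- function(x, size) writeBin(as.integer(x), con, size = size,
                                      endian = "little")
  ## header
  writeChar("II", con, nchars = 2, eos = NULL)
  w_int(42L, 2)
  first_ifd_pos_placeholder <- seek(con)
  w_int(0L, 4)  # patched later
  page_meta <- vector("list", length(pages))
  for (p in seq_along(pages)) {
    data_off <- seek(con)
    m <- pages[[p]]
    v <- as.numeric(t(m))  # TIFF is row-major
    if (format == "float32") {
      writeBin(v, con, size = 4, endian = "little")
    } else {
      v <- pmin(pmax(round(v), 0), 2^bits - 1)
      w_int(v, bytes_pp)
    }
    page_meta[[p]] <- list(data_off = data_off,
                           n_bytes = length(v) * bytes_pp)
  }
  desc_raw <- NULL
  desc_off <- 0L
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0))
    desc_off <- seek(con)
    writeBin(desc_raw, con)
    if (length(desc_raw) %% 2 == 1) writeBin(as.raw(0), con)
  }
  ifd_offsets <- integer(length(pages))
  for (p in seq_along(pages)) {
    ifd_offsets[p] <- seek(con)
    entries <- list(
      list(TIFF_TAGS[["width"]], 3L, 1L, nx),
      list(TIFF_TAGS[["length"]], 3L, 1L, ny),
      list(TIFF_TAGS[["bits"]], 3L, 1L, bits),
      list(TIFF_TAGS[["compression"]], 3L, 1L, 1L),
      list(TIFF_TAGS[["photometric"]], 3L, 1L, 1L),
      list(TIFF_TAGS[["strip_offsets"]], 4L, 1L, page_meta[[p]]$data_off),
      list(TIFF_TAGS[["samples"]], 3L, 1L, 1L),
      list(TIFF_TAGS[["rows_per_strip"]], 3L, 1L, ny),
      list(TIFF_TAGS[["strip_bytes"]], 4L, 1L, page_meta[[p]]$n_bytes),
      list(TIFF_TAGS[["sample_format"]], 3L, 1L, fmt_code))
    if (p == 1L && !is.null(desc_raw))
      entries <- append(entries, list(
        list(TIFF_TAGS[["description"]], 2L, length(desc_raw), desc_off)),
        after = 5L)
    entries <- entries[order(vapply(entries, `[[`, integer(1), 1L))]
    w_int(length(entries), 2)
    for (e in entries) {
      w_int(e[[1]], 2); w_int(e[[2]], 2); w_int(e[[3]], 4)
      if (e[[2]] == 3L && e[[3]] == 1L) {  # SHORT packed into 4 bytes
        w_int(e[[4]], 2); w_int(0L, 2)
      } else {
        w_int(e[[4]], 4)
      }
    }
    ## next-IFD pointer: patched after the fact for all but the last page
    w_int(0L, 4)
  }
  ## patch the IFD chain
  seek(con, first_ifd_pos_placeholder, rw = "write")
  w_int(ifd_offsets[1], 4)
  ifd_sizes <- vapply(seq_along(pages), function(p) {
    n_entries <- 10L + as.integer(p == 1L && !is.null(desc_raw))
    2L + n_entries * 12L
  }, integer(1))
  for (p in seq_len(length(pages) - 1L)) {
    seek(con, ifd_offsets[p] + ifd_sizes[p], rw = "write")
    w_int(ifd_offsets[p + 1], 4)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_tiff()]
#'
#' Supports the baseline subset: little-endian, uncompressed, one sample
#' per pixel, single strip, 8/16-bit unsigned or 32-bit float.
#'
#' @param path TIFF file.
#' @return list of numeric matrices; attribute `description` if present.
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  u <- function(off, size) {
    ## little-endian unsigned integer at 0-based byte offset
    sum(as.integer(raw_all[(off + 1):(off + size)]) * 256^(0:(size - 1)))
  }
  if (rawToChar(raw_all[1:2]) != "II" || u(2, 2) != 42L)
    sp_stop("invalid_tiff", "not a little-endian TIFF")
  ifd_off <- u(4, 4)
  pages <- list()
  description <- NULL
  while (ifd_off != 0) {
    n <- u(ifd_off, 2)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- u(e, 2); typ <- u(e + 2, 2); cnt <- u(e + 4, 4)
      val <- if (typ == 3L && cnt == 1L) u(e + 8, 2) else u(e + 8, 4)
      tags[[as.character(tag)]] <- list(type = typ, count = cnt, value = val)
    }
    g <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) default else t$value
    }
    nx <- g(256); ny <- g(257); bits <- g(258, 1L)
    if (g(259, 1L) != 1L) sp_stop("invalid_tiff", "compressed TIFF unsupported")
    fmt <- g(339, 1L)
    off <- g(273); nbytes <- g(279)
    if (is.null(description) && !is.null(tags[["270"]])) {
      d <- tags[["270"]]
      bytes <- raw_all[(d$value + 1):(d$value + d$count)]
      description <- rawToChar(bytes[bytes != as.raw(0)])
    }
    npx <- nx * ny
    buf <- raw_all[(off + 1):(off + nbytes)]
    v <- if (fmt == 3L) {
      readBin(buf, "numeric", n = npx, size = 4, endian = "little")
    } else {
      as.numeric(readBin(buf, "integer", n = npx, size = bits / 8,
                         signed = FALSE, endian = "little"))
    }
    pages[[length(pages) + 1L]] <- t(matrix(v, nx, ny))
    ifd_off <- u(ifd_off + 2 + n * 12, 4)
  }
  attr(pages, "description") <- description
  pages
}

#' Write a scene (and optional ground truth) to disk
#'
#' Produces `<name>.tif` (pages in TZC order, float32),
#' `<name>.truth.json` (coordinates in 0-based pixels, calibration
#' recorded separately) and `<name>.labels.tif` (uint8 label raster:
#' 1 = T cell, 2 = APC) when truth is supplied.
#'
#' @param scene an [image_scene].
#' @param dir output directory (created if missing).
#' @param name scene basename.
#' @param truth optional ground-truth list from a generator.
#' @return named character vector of the files written.
#' @export
write_scene <- function(scene, dir, name, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(scene$data)
  pages <- list()
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ci in seq_len(d[3]))
    pages[[length(pages) + 1L]] <- matrix(scene$data[t, z, ci, , ],
                                          d[4], d[5])
  desc <- sprintf("axes=TZCYX;t=%d;z=%d;c=%d;roles=%s;pixel_size=%g;z_step=%g;frame_interval=%g",
                  d[1], d[2], d[3],
                  paste(sprintf("%s:%d", names(scene$channel_roles),
                                scene$channel_roles), collapse = ","),
                  scene$pixel_size, scene$z_step, scene$frame_interval)
  img_path <- file.path(dir, paste0(name, ".tif"))
  write_tiff(img_path, pages, description = desc)
  out <- c(image = img_path)
  if (!is.null(truth)) {
    tr <- truth
    json_path <- file.path(dir, paste0(name, ".truth.json"))
    ## masks and 3D rasters go to the label TIFF, not the JSON sidecar
    keep <- !vapply(tr, function(x)
      (is.array(x) || is.matrix(x)) &&
        (is.logical(x) || length(dim(x)) > 2), logical(1))
    jsonlite::write_json(tr[keep], json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out["truth"] <- json_path
    if (!is.null(tr$cell_mask) && length(dim(tr$cell_mask)) == 2) {
      lab <- matrix(0, nrow(tr$cell_mask), ncol(tr$cell_mask))
      lab[tr$cell_mask] <- 1
      if (!is.null(tr$apc_mask)) lab[tr$apc_mask] <- 2
      lab_path <- file.path(dir, paste0(name, ".labels.tif"))
      write_tiff(lab_path, lab, format = "uint8")
      out["labels"] <- lab_path
    }
  }
  out
}

#' Read a scene written by [write_scene()]
#' @param path path to the `<name>.tif` image.
#' @return an [image_scene].
#' @export
read_scene <- function(path) {
  pages <- read_tiff(path)
  desc <- attr(pages, "description")
  if (is.null(desc)) sp_stop("invalid_tiff", "missing axis description")
  kv <- strsplit(strsplit(desc, ";")[[1]], "=")
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  n_t <- as.integer(vals[["t"]]); n_z <- as.integer(vals[["z"]])
  n_c <- as.integer(vals[["c"]])
  roles_kv <- strsplit(strsplit(vals[["roles"]], ",")[[1]], ":")
  roles <- stats::setNames(as.integer(vapply(roles_kv, `[`, character(1), 2)),
                           vapply(roles_kv, `[`, character(1), 1))
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, dim = c(n_t, n_z, n_c, ny, nx))
  p <- 1L
  for (t in seq_len(n_t)) for (z in seq_len(n_z)) for (ci in seq_len(n_c)) {
    data[t, z, ci, , ] <- pages[[p]]
    p <- p + 1L
  }
  image_scene(data, roles, as.numeric(vals[["pixel_size"]]),
              as.numeric(vals[["z_step"]]),
              as.numeric(vals[["frame_interval"]]))
}
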