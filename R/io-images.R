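# Image I/O.
#
# TIFF carries the pixel data; physical calibration (pixel/voxel sizes,
# channel names, polarity) travels in a JSON sidecar next to the image
# (<image>.json), because baseline TIFF writers do not expose custom
# resolution tags portably. Integer-valued data in [0, 65535] is stored as
# 16-bit samples and round-trips bit-exactly; anything else is stored as
# 32-bit float after an affine map to [0,1] that is inverted on read.

sidecar_path <- function(path) paste0(path, ".json")

encode_pages <- function(values) {
  lo <- min(values); hi <- max(values)
  integral <- all(values == round(values)) && lo >= 0 && hi <= 65535
  if (integral) {
    list(mode = "uint16", lo = 0, hi = 65535,
         scale = function(m) m / 65535, bits = 16L)
  } else {
    span <- if (hi > lo) hi - lo else 1
    list(mode = "float32", lo = lo, hi = hi,
         scale = function(m) (m - lo) / span, bits = 32L)
  }
}

decode_pages <- function(pages, meta) {
  if (identical(meta$mode, "uint16")) {
    lapply(pages, function(p) round(p * 65535))
  } else {
    span <- if (meta$hi > meta$lo) meta$hi - meta$lo else 1
    lapply(pages, function(p) p * span + meta$lo)
  }
}

#' Write a calibrated well image to TIFF (+ JSON sidecar)
#'
#' @param image a \code{CalibratedImage2D}.
#' @param path output TIFF path; calibration is written to
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_well_tiff <- function(image, path) {
  validate_calibration(image)
  enc <- encode_pages(image$intensities)
  tiff::writeTIFF(enc$scale(image$intensities), path,
                  bits.per.sample = enc$bits, compression = "none",
                  reduce = FALSE)
  meta <- list(type = "CalibratedImage2D", mode = enc$mode,
               lo = enc$lo, hi = enc$hi,
               storage_mode = storage.mode(image$intensities),
               pixel_size_um = image$pixel_size_um,
               polarity = image$polarity, well_id = image$well_id)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a well image from TIFF or PNG
#'
#' TIFF written by [write_well_tiff()] restores calibration from the JSON
#' sidecar; for foreign TIFF/PNG files (no sidecar) the pixel size must be
#' supplied. RGB files are collapsed with [to_grayscale()]. PNG/foreign
#' files are returned on the 8-bit scale (0-255).
#'
#' @param path image file (.tif/.tiff/.png).
#' @param pixel_size_um overrides (or supplies) the pixel size in um.
#' @param channel_rule passed to [to_grayscale()] for RGB input.
#' @param polarity,well_id calibration for files without a sidecar.
#' @return a \code{CalibratedImage2D}.
#' @export
read_well_image <- function(path, pixel_size_um = NULL,
                            channel_rule = "min",
                            polarity = "dark_spots_on_light",
                            well_id = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  sc <- sidecar_path(path)
  if (ext %in% c("tif", "tiff") && file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    m <- decode_pages(list(tiff::readTIFF(path)), meta)[[1L]]
    if (!is.null(meta$storage_mode)) storage.mode(m) <- meta$storage_mode
    return(calibrated_image_2d(
      m,
      pixel_size_um = if (is.null(pixel_size_um)) meta$pixel_size_um else pixel_size_um,
      polarity = if (is.null(meta$polarity)) polarity else meta$polarity,
      well_id = if (is.null(well_id)) meta$well_id else well_id))
  }
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = tiff::readTIFF(path),
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "': ", path))
  if (is.null(pixel_size_um))
    stop("no calibration sidecar for ", path,
         "; pixel_size_um must be given")
  if (is.array(raw) && length(dim(raw)) == 3L && dim(raw)[3L] %in% c(2L, 4L))
    raw <- raw[, , seq_len(dim(raw)[3L] - 1L), drop = FALSE]  # drop alpha
  if (is.array(raw) && length(dim(raw)) == 3L && dim(raw)[3L] == 1L)
    raw <- raw[, , 1L]
  to_grayscale(raw * 255, channel_rule = channel_rule,
               pixel_size_um = pixel_size_um, polarity = polarity,
               well_id = if (is.null(well_id))
                 tools::file_path_sans_ext(basename(path)) else well_id)
}

#' Write a calibrated multi-channel stack to multi-page TIFF (+ sidecar)
#'
#' Pages are ordered channel-major: all z-planes of the first channel, then
#' the next channel. The sidecar records channel names, dimensions, voxel
#' sizes and the intensity encoding.
#'
#' @param stack a \code{CalibratedStack3D}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  validate_calibration(stack)
  d <- dim(stack$channels[[1L]])
  all_vals <- unlist(stack$channels, use.names = FALSE)
  enc <- encode_pages(all_vals)
  pages <- list()
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    for (z in seq_len(d[1L]))
      pages[[length(pages) + 1L]] <- enc$scale(a[z, , ])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = enc$bits,
                  compression = "none", reduce = FALSE)
  meta <- list(type = "CalibratedStack3D", mode = enc$mode,
               lo = enc$lo, hi = enc$hi,
               storage_mode = storage.mode(all_vals),
               dims_zyx = d, channels = names(stack$channels),
               voxel_size_um = stack$voxel_size_um,
               chamber_id = stack$chamber_id)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated multi-channel stack from multi-page TIFF
#'
#' @param path TIFF written by [write_stack_tiff()], or a foreign
#'   multi-page TIFF (then \code{voxel_size_um} and \code{channels} give
#'   the calibration, pages assumed channel-major).
#' @param voxel_size_um optional \code{c(dz, dy, dx)} override in um.
#' @param channels optional channel names for foreign files.
#' @param chamber_id optional chamber label.
#' @return a \code{CalibratedStack3D}.
#' @export
read_stack_tiff <- function(path, voxel_size_um = NULL, channels = NULL,
                            chamber_id = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    pages <- decode_pages(pages, meta)
    d <- as.integer(meta$dims_zyx)
    chn <- meta$channels
    vs <- if (is.null(voxel_size_um)) meta$voxel_size_um else voxel_size_um
    cid <- if (is.null(chamber_id)) meta$chamber_id else chamber_id
  } else {
    if (is.null(voxel_size_um) || is.null(channels))
      stop("no calibration sidecar for ", path,
           "; voxel_size_um and channels must be given")
    chn <- channels
    nz <- length(pages) / length(chn)
    if (nz != round(nz))
      stop("page count ", length(pages), " is not a multiple of ",
           length(chn), " channels")
    d <- c(as.integer(nz), dim(pages[[1L]]))
    vs <- voxel_size_um
    cid <- if (is.null(chamber_id))
      tools::file_path_sans_ext(basename(path)) else chamber_id
    pages <- lapply(pages, function(p) p * 255)
  }
  nz <- d[1L]
  chs <- list()
  for (i in seq_along(chn)) {
    a <- array(0, dim = d)
    for (z in seq_len(nz)) a[z, , ] <- pages[[(i - 1L) * nz + z]]
    if (exists("meta", inherits = FALSE) && !is.null(meta$storage_mode))
      storage.mode(a) <- meta$storage_mode
    chs[[chn[i]]] <- a
  }
  calibrated_stack_3d(chs, voxel_size_um = vs, chamber_id = cid)
}
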