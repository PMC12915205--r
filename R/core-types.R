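#' Calibrated 2D well image
#'
#' Container for a single-channel well image (e.g. an ELISPOT membrane
#' photograph) together with its physical pixel size. All downstream
#' measurements are reported in micrometres via \code{pixel_size_um}.
#'
#' @param intensities numeric matrix of finite intensities (rows = y,
#'   columns = x). Arbitrary intensity units; computation is always done in
#'   double precision regardless of the acquisition bit depth.
#' @param pixel_size_um positive scalar, micrometres per pixel (isotropic).
#' @param polarity either \code{"dark_spots_on_light"} (the usual enzymatic
#'   ELISPOT readout: cytokine spots are darker than the membrane) or
#'   \code{"light_spots_on_dark"} (fluorescent readouts).
#' @param well_id character label carried into every report.
#' @return an object of class \code{CalibratedImage2D}.
#' @seealso [calibrated_stack_3d()], [validate_calibration()]
#' @export
calibrated_image_2d <- function(intensities,
                                pixel_size_um,
                                polarity = c("dark_spots_on_light",
                                             "light_spots_on_dark"),
                                well_id = "well") {
  polarity <- match.arg(polarity)
  obj <- structure(
    list(intensities = intensities,
         pixel_size_um = pixel_size_um,
         polarity = polarity,
         well_id = as.character(well_id)),
    class = "CalibratedImage2D")
  validate_calibration(obj)
}

#' Calibrated multi-channel 3D confocal stack
#'
#' Container for an anisotropic confocal z-stack. Channels are named 3D
#' arrays in \code{(z, y, x)} axis order sharing one voxel grid; voxel edge
#' lengths are given per axis in micrometres, so \code{dz > dx} (the common
#' confocal anisotropy) is handled everywhere in physical units.
#'
#' Physical positions are voxel-centre positions: the centre of the voxel
#' with 0-based index \code{i} along an axis of spacing \code{d} lies at
#' \code{(i + 0.5) * d} micrometres.
#'
#' @param channels named list of 3D numeric arrays, identical dimensions.
#'   The infiltration pipeline resolves the roles \code{"tcell"} and
#'   \code{"organoid"} by name.
#' @param voxel_size_um numeric triple \code{c(dz, dy, dx)}, micrometres.
#' @param chamber_id character label for the tissue chamber.
#' @return an object of class \code{CalibratedStack3D}.
#' @export
calibrated_stack_3d <- function(channels, voxel_size_um, chamber_id = "chamber") {
  obj <- structure(
    list(channels = channels,
         voxel_size_um = as.numeric(voxel_size_um),
         chamber_id = as.character(chamber_id)),
    class = "CalibratedStack3D")
  validate_calibration(obj)
}

#' 3D spot-detection parameters
#'
#' Expected T-cell extents used by [detect_tcells_3d()]: an XY diameter of
#' 5 um and a Z height of 10 um describe a typical lymphocyte imaged with a
#' coarser axial point-spread function. The detection floor is expressed as
#' a quantile of the smoothed response so it adapts to the intensity scale.
#'
#' @param xy_diameter_um expected in-plane cell diameter, micrometres.
#' @param z_height_um expected axial cell extent, micrometres.
#' @param min_intensity_quantile fraction in (0,1); response quantile below
#'   which candidate maxima are discarded.
#' @return an object of class \code{DetectionParams3D}.
#' @export
detection_params_3d <- function(xy_diameter_um = 5,
                                z_height_um = 10,
                                min_intensity_quantile = 0.99) {
  stopifnot(is.numeric(xy_diameter_um), length(xy_diameter_um) == 1L,
            is.finite(xy_diameter_um), xy_diameter_um > 0,
            is.numeric(z_height_um), length(z_height_um) == 1L,
            is.finite(z_height_um), z_height_um > 0,
            is.numeric(min_intensity_quantile),
            length(min_intensity_quantile) == 1L,
            min_intensity_quantile > 0, min_intensity_quantile < 1)
  structure(list(xy_diameter_um = xy_diameter_um,
                 z_height_um = z_height_um,
                 min_intensity_quantile = min_intensity_quantile),
            class = "DetectionParams3D")
}

#' Spot size-filter range
#'
#' Inclusive physical-area bounds used to separate true cytokine spots from
#' artifacts (membrane debris, fibres, staining blotches). The default
#' \code{[40, 4000]} um^2 corresponds to spot equivalent diameters of about
#' 7-71 um, spanning typical ELISPOT spot sizes; every report echoes the
#' range actually applied so no filtering is ever implicit.
#'
#' @param min_area_um2 non-negative lower area bound, um^2 (inclusive).
#' @param max_area_um2 positive upper area bound, um^2 (inclusive).
#' @return an object of class \code{SizeFilterRange}.
#' @export
size_filter_range <- function(min_area_um2 = 40, max_area_um2 = 4000) {
  stopifnot(is.numeric(min_area_um2), length(min_area_um2) == 1L,
            is.finite(min_area_um2), min_area_um2 >= 0,
            is.numeric(max_area_um2), length(max_area_um2) == 1L,
            is.finite(max_area_um2), max_area_um2 > 0)
  if (!(min_area_um2 < max_area_um2))
    stop("min_area_um2 must be strictly less than max_area_um2")
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2),
            class = "SizeFilterRange")
}

#' Infiltration depth window
#'
#' Signed-distance window defining an infiltrated T-cell: negative distances
#' are inside the organoid surface. The defaults \code{[-200, 0]} um count a
#' cell as infiltrated when it is in contact with the surface (0 um) or
#' inside it down to a depth of 200 um; deeper cells are reported separately
#' as \code{excluded_deep}.
#'
#' @param d_min_um lower signed-distance bound, um (inclusive).
#' @param d_max_um upper signed-distance bound, um (inclusive).
#' @return an object of class \code{DepthWindow}.
#' @export
depth_window <- function(d_min_um = -200, d_max_um = 0) {
  stopifnot(is.numeric(d_min_um), length(d_min_um) == 1L, is.finite(d_min_um),
            is.numeric(d_max_um), length(d_max_um) == 1L, is.finite(d_max_um))
  if (!(d_min_um < d_max_um))
    stop("d_min_um must be strictly less than d_max_um")
  structure(list(d_min_um = d_min_um, d_max_um = d_max_um,
                 convention = "negative = inside the organoid surface"),
            class = "DepthWindow")
}

#' Validate a calibrated image or stack
#'
#' Checks every type invariant (finite intensities, positive physical
#' calibration, matching channel dimensions) and returns the object
#' unchanged when all hold.
#'
#' @param obj a \code{CalibratedImage2D} or \code{CalibratedStack3D}.
#' @return \code{obj}, invisibly unchanged, if valid; otherwise an error
#'   naming the violated invariant.
#' @export
validate_calibration <- function(obj) {
  UseMethod("validate_calibration")
}

#' @export
validate_calibration.CalibratedImage2D <- function(obj) {
  if (!is.matrix(obj$intensities) || !is.numeric(obj$intensities))
    stop("intensities must be a numeric matrix")
  if (any(dim(obj$intensities) < 1L))
    stop("intensity grid must be non-empty")
  if (!all(is.finite(obj$intensities)))
    stop("intensities contain non-finite values (NaN/Inf)")
  p <- obj$pixel_size_um
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0)
    stop("pixel_size_um must be a positive finite scalar, got ",
         deparse(substitute(p)), " = ", format(p))
  if (!obj$polarity %in% c("dark_spots_on_light", "light_spots_on_dark"))
    stop("unknown polarity: ", obj$polarity)
  obj
}

#' @export
validate_calibration.CalibratedStack3D <- function(obj) {
  ch <- obj$channels
  if (!is.list(ch) || length(ch) == 0L || is.null(names(ch)) ||
      any(!nzchar(names(ch))))
    stop("channels must be a non-empty named list")
  dims <- lapply(ch, dim)
  for (i in seq_along(ch)) {
    if (!is.array(ch[[i]]) || length(dims[[i]]) != 3L)
      stop("channel '", names(ch)[i], "' is not a 3D array")
    if (!all(is.finite(ch[[i]])))
      stop("channel '", names(ch)[i], "' contains non-finite values")
  }
  ref <- dims[[1L]]
  for (i in seq_along(ch)) {
    if (!identical(dims[[i]], ref))
      stop("channel dimensions differ: '", names(ch)[1L], "' is ",
           paste(ref, collapse = "x"), " but '", names(ch)[i], "' is ",
           paste(dims[[i]], collapse = "x"))
  }
  v <- obj$voxel_size_um
  if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v)) || any(v <= 0))
    stop("voxel_size_um must be three positive finite values (dz, dy, dx), got ",
         paste(format(v), collapse = ", "))
  obj
}

#' @export
validate_calibration.default <- function(obj) {
  stop("validate_calibration: unsupported object of class ",
       paste(class(obj), collapse = "/"))
}

# Resolve a channel role by name; errors list what is available.
get_channel <- function(stack, role) {
  ch <- stack$channels[[role]]
  if (is.null(ch))
    stop("stack '", stack$chamber_id, "' has no channel named '", role,
         "' (available: ", paste(names(stack$channels), collapse = ", "), ")")
  ch
}

#' Collapse a possibly-RGB raster to a calibrated grayscale image
#'
#' Membrane photographs may arrive as RGB; the spot-calling engine operates
#' on one channel. For 3-channel input the \code{channel_rule} selects the
#' reduction: \code{"min"} (default) takes the per-pixel minimum across
#' channels so that spots that are dark in any channel stay dark;
#' \code{"luminance"} uses Rec. 601 weights (0.299, 0.587, 0.114);
#' \code{"red"}/\code{"green"}/\code{"blue"} pick one channel.
#'
#' @param raster numeric matrix (1 channel) or H x W x 3 array (RGB).
#' @param channel_rule reduction rule for 3-channel input.
#' @param pixel_size_um,polarity,well_id calibration passed through to
#'   [calibrated_image_2d()].
#' @return a \code{CalibratedImage2D}. Single-channel input is returned
#'   unchanged up to containerisation (idempotent).
#' @export
to_grayscale <- function(raster,
                         channel_rule = c("min", "luminance",
                                          "red", "green", "blue"),
                         pixel_size_um = 1,
                         polarity = "dark_spots_on_light",
                         well_id = "well") {
  channel_rule <- match.arg(channel_rule)
  if (inherits(raster, "CalibratedImage2D")) return(raster)
  if (is.matrix(raster)) {
    gray <- raster
  } else if (is.array(raster) && length(dim(raster)) == 3L) {
    nch <- dim(raster)[3L]
    if (nch == 1L) {
      gray <- raster[, , 1L]
    } else if (nch == 3L) {
      gray <- switch(channel_rule,
        min       = pmin(raster[, , 1L], raster[, , 2L], raster[, , 3L]),
        luminance = 0.299 * raster[, , 1L] + 0.587 * raster[, , 2L] +
                    0.114 * raster[, , 3L],
        red       = raster[, , 1L],
        green     = raster[, , 2L],
        blue      = raster[, , 3L])
    } else {
      stop("unsupported channel count: raster is ",
           paste(dim(raster), collapse = "x"),
           " (expected 1 or 3 channels)")
    }
  } else {
    stop("raster must be a matrix or an H x W x C array, got ",
         paste(class(raster), collapse = "/"))
  }
  calibrated_image_2d(gray, pixel_size_um = pixel_size_um,
                      polarity = polarity, well_id = well_id)
}

#' @export
print.CalibratedImage2D <- function(x, ...) {
  cat("CalibratedImage2D '", x$well_id, "': ",
      nrow(x$intensities), " x ", ncol(x$intensities), " px @ ",
      format(x$pixel_size_um), " um/px, ", x$polarity, "\n", sep = "")
  invisible(x)
}

#' @export
print.CalibratedStack3D <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat("CalibratedStack3D '", x$chamber_id, "': ",
      paste(d, collapse = " x "), " voxels (z,y,x) @ (",
      paste(format(x$voxel_size_um), collapse = ", "),
      ") um, channels: ", paste(names(x$channels), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
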