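# ELISPOT spot calling.
#
# Pipeline: adaptive (local-mean) thresholding isolates pixels darker than
# their neighbourhood, morphological cleanup removes speckle and closes
# gaps, connected-component labelling identifies candidate spots, and a
# physical size filter separates true cytokine spots from artifacts. Each
# stage is exposed on its own so intermediate masks can be inspected.

reflect_pad <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(r:1, 1:nr, nr:(nr - r + 1L)), c(r:1, 1:nc, nc:(nc - r + 1L)), drop = FALSE]
}

# Local mean over a (2r+1)^2 window via a summed-area table on the
# reflect-padded image; exact (no FFT) and O(n) in the pixel count.
local_mean <- function(m, r) {
  p <- reflect_pad(m, r)
  S <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  S[-1L, -1L] <- apply(apply(p, 2L, cumsum), 1L, cumsum) |> t()
  w <- 2L * r + 1L
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr); ci <- seq_len(nc)
  (S[ri + w, ci + w, drop = FALSE] - S[ri, ci + w, drop = FALSE] -
     S[ri + w, ci, drop = FALSE] + S[ri, ci, drop = FALSE]) / (w * w)
}

#' Adaptive local-mean threshold
#'
#' A pixel is foreground when its intensity differs from the mean of its
#' \code{(2r+1) x (2r+1)} neighbourhood by more than \code{offset} in the
#' spot direction: below the local mean for \code{dark_spots_on_light}
#' images, above it for \code{light_spots_on_dark}. Borders are handled by
#' symmetric reflection, so no rim of the membrane is lost. A local
#' statistic (rather than one global threshold) makes the segmentation
#' insensitive to illumination gradients across the well.
#'
#' @param image a \code{CalibratedImage2D}.
#' @param window_radius_px neighbourhood radius r in pixels (window edge
#'   \code{2r+1}); must be smaller than both image dimensions.
#' @param offset intensity offset below/above the local mean required to
#'   call a pixel foreground. Larger values reject more noise; it should
#'   exceed roughly 3 standard deviations of the pixel noise.
#' @return a \code{BinaryMask2D}: logical matrix plus the provenance of the
#'   parameters that produced it.
#' @export
adaptive_threshold <- function(image, window_radius_px = 25, offset = 5) {
  validate_calibration(image)
  r <- as.integer(window_radius_px)
  if (r < 1L) stop("window_radius_px must be >= 1")
  m <- image$intensities
  if (r >= nrow(m) || r >= ncol(m))
    stop("window radius ", r, " px does not fit the ", nrow(m), "x", ncol(m),
         " px image")
  mu <- local_mean(m, r)
  mask <- if (image$polarity == "dark_spots_on_light")
    m < mu - offset else m > mu + offset
  structure(list(mask = mask,
                 provenance = list(stage = "adaptive_threshold",
                                   window_radius_px = r, offset = offset,
                                   polarity = image$polarity)),
            class = "BinaryMask2D")
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "BinaryMask2D")) mask$mask
  else if (is.matrix(mask)) mask > 0 else stop("not a 2D mask")
}

#' Morphological cleanup of a binary mask
#'
#' Fixed order: opening (removes speckle smaller than the structuring
#' element), then closing (bridges small gaps inside spots), then optional
#' hole filling. Disc-shaped structuring elements; a radius of 0 skips that
#' step. Hole filling matters for large spots segmented by an adaptive
#' threshold whose window is smaller than the spot: their interior can come
#' out hollow and is recovered here.
#'
#' @param mask a \code{BinaryMask2D} or logical matrix.
#' @param opening_radius_px,closing_radius_px structuring-element radii (px).
#' @param fill_holes fill background regions not connected to the border.
#' @return a \code{BinaryMask2D}.
#' @export
morphological_clean <- function(mask, opening_radius_px = 1,
                                closing_radius_px = 1, fill_holes = TRUE) {
  m <- as_mask_matrix(mask)
  stopifnot(opening_radius_px >= 0, closing_radius_px >= 0)
  x <- m * 1
  if (opening_radius_px > 0)
    x <- EBImage::opening(x, EBImage::makeBrush(2L * opening_radius_px + 1L, "disc"))
  if (closing_radius_px > 0)
    x <- EBImage::closing(x, EBImage::makeBrush(2L * closing_radius_px + 1L, "disc"))
  if (fill_holes)
    x <- EBImage::fillHull(x)
  prov <- if (inherits(mask, "BinaryMask2D")) mask$provenance else list()
  prov$morphology <- list(opening_radius_px = opening_radius_px,
                          closing_radius_px = closing_radius_px,
                          fill_holes = fill_holes)
  structure(list(mask = as.matrix(x) > 0.5, provenance = prov),
            class = "BinaryMask2D")
}

#' Connected-component labelling
#'
#' Partitions the foreground into maximal connected regions. Labels
#' \code{1..K} are assigned in array storage order of each component's
#' first pixel, so the labelling is deterministic.
#'
#' @param mask a \code{BinaryMask2D} or logical matrix.
#' @param connectivity 8 (edge + diagonal neighbours, default: diagonal
#'   pixel runs stay one spot) or 4 (edge neighbours only).
#' @return integer matrix of labels, 0 = background, with attribute
#'   \code{n_components}.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- as_mask_matrix(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- .cc_label(as.logical(m), dim(m), as.integer(connectivity))
  out <- matrix(lab, nrow(m), ncol(m))
  attr(out, "n_components") <- attr(lab, "n_components")
  out
}

component_areas_px <- function(labels) {
  k <- n_labels(labels)
  if (k == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = k)
}

n_labels <- function(labels) {
  k <- attr(labels, "n_components")
  if (is.null(k)) k <- max(0L, labels)
  as.integer(k)
}

#' Physical size filtration of labelled components
#'
#' Partitions components by physical area into accepted spots and
#' rejected small/large artifacts, with inclusive bounds at both ends of
#' the range. The partition is exhaustive: every label lands in exactly
#' one class.
#'
#' @param labels label matrix from [label_components()].
#' @param pixel_size_um pixel size in um.
#' @param range a \code{SizeFilterRange}.
#' @return list with integer label vectors \code{accepted},
#'   \code{rejected_small}, \code{rejected_large} and the per-label
#'   \code{area_um2}.
#' @export
filter_by_size <- function(labels, pixel_size_um, range = size_filter_range()) {
  stopifnot(inherits(range, "SizeFilterRange"))
  areas_um2 <- component_areas_px(labels) * pixel_size_um^2
  ids <- seq_along(areas_um2)
  small <- areas_um2 < range$min_area_um2
  large <- areas_um2 > range$max_area_um2
  list(accepted = ids[!small & !large],
       rejected_small = ids[small],
       rejected_large = ids[large],
       area_um2 = areas_um2)
}

#' Per-spot measurements
#'
#' One record per labelled component: pixel and physical area, centroid
#' (unweighted, in pixels and um), equivalent circular diameter, mean
#' intensity over member pixels, and the eccentricity of the
#' second-moment ellipse (0 for a circle, approaching 1 for a line).
#'
#' @param labels label matrix from [label_components()].
#' @param image the source \code{CalibratedImage2D} (or intensity matrix).
#' @param pixel_size_um pixel size in um (taken from \code{image} when it
#'   is calibrated).
#' @return data.frame with one row per label.
#' @export
measure_spots <- function(labels, image, pixel_size_um = NULL) {
  if (inherits(image, "CalibratedImage2D")) {
    if (is.null(pixel_size_um)) pixel_size_um <- image$pixel_size_um
    img <- image$intensities
  } else img <- image
  if (!identical(dim(labels), dim(img)))
    stop("labels (", paste(dim(labels), collapse = "x"), ") and image (",
         paste(dim(img), collapse = "x"), ") differ in shape")
  k <- n_labels(labels)
  empty <- data.frame(spot_id = integer(0), centroid_row_px = numeric(0),
                      centroid_col_px = numeric(0), centroid_y_um = numeric(0),
                      centroid_x_um = numeric(0), area_px = integer(0),
                      area_um2 = numeric(0), equivalent_diameter_um = numeric(0),
                      mean_intensity = numeric(0), eccentricity = numeric(0))
  if (k == 0L) return(empty)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  s <- rowsum(cbind(1, rr, cc, rr * rr, cc * cc, rr * cc, img[idx]),
              group = lab, reorder = TRUE)
  area <- s[, 1L]
  mr <- s[, 2L] / area; mc <- s[, 3L] / area
  # central second moments
  mu_rr <- s[, 4L] / area - mr^2
  mu_cc <- s[, 5L] / area - mc^2
  mu_rc <- s[, 6L] / area - mr * mc
  tr <- mu_rr + mu_cc
  det_ <- mu_rr * mu_cc - mu_rc^2
  disc <- pmax(0, tr^2 / 4 - det_)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- tr / 2 - sqrt(disc)
  ecc <- ifelse(l1 > 0, sqrt(pmax(0, 1 - l2 / l1)), 0)
  area_um2 <- area * pixel_size_um^2
  data.frame(spot_id = as.integer(rownames(s)),
             centroid_row_px = mr, centroid_col_px = mc,
             centroid_y_um = (mr - 0.5) * pixel_size_um,
             centroid_x_um = (mc - 0.5) * pixel_size_um,
             area_px = as.integer(area), area_um2 = area_um2,
             equivalent_diameter_um = 2 * sqrt(area_um2 / pi),
             mean_intensity = s[, 7L] / area,
             eccentricity = ecc)
}

#' ELISPOT analysis parameters
#'
#' Full parameter set for [count_spots()]; every value is echoed into the
#' report so no default is ever applied silently.
#'
#' @param window_radius_px,offset see [adaptive_threshold()].
#' @param opening_radius_px,closing_radius_px,fill_holes see
#'   [morphological_clean()].
#' @param connectivity see [label_components()].
#' @param size_filter a \code{SizeFilterRange}.
#' @param exclude_border drop components touching the image border before
#'   filtration (off by default; edge wells may clip spots).
#' @param channel_rule RGB reduction rule, see [to_grayscale()].
#' @return a named list of class \code{ElispotParams}.
#' @export
elispot_params <- function(window_radius_px = 25, offset = 5,
                           opening_radius_px = 1, closing_radius_px = 1,
                           fill_holes = TRUE, connectivity = 8,
                           size_filter = size_filter_range(),
                           exclude_border = FALSE, channel_rule = "min") {
  stopifnot(inherits(size_filter, "SizeFilterRange"))
  structure(list(window_radius_px = window_radius_px, offset = offset,
                 opening_radius_px = opening_radius_px,
                 closing_radius_px = closing_radius_px,
                 fill_holes = fill_holes, connectivity = connectivity,
                 size_filter = size_filter, exclude_border = exclude_border,
                 channel_rule = channel_rule),
            class = "ElispotParams")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Count cytokine spots in a well image
#'
#' End-to-end spot calling: grayscale conversion, adaptive thresholding,
#' morphological cleanup, connected-component labelling, physical size
#' filtration, and per-spot measurement. Deterministic: identical input
#' and parameters give an identical report.
#'
#' @param image a \code{CalibratedImage2D} (or RGB array together with
#'   \code{pixel_size_um} via [to_grayscale()] beforehand).
#' @param params an \code{ElispotParams} set.
#' @return a \code{SpotReport}: counts (labelled / accepted / rejected
#'   small / rejected large), accepted-size statistics and histogram, one
#'   record per component with its accepted flag, and the full parameter
#'   echo.
#' @export
count_spots <- function(image, params = elispot_params()) {
  stopifnot(inherits(params, "ElispotParams"))
  image <- with_stage("to_grayscale",
                      to_grayscale(if (inherits(image, "CalibratedImage2D"))
                        image else image,
                        channel_rule = params$channel_rule))
  mask <- with_stage("adaptive_threshold",
                     adaptive_threshold(image, params$window_radius_px,
                                        params$offset))
  mask <- with_stage("morphological_clean",
                     morphological_clean(mask, params$opening_radius_px,
                                         params$closing_radius_px,
                                         params$fill_holes))
  labels <- with_stage("label_components",
                       label_components(mask, params$connectivity))
  n_excluded_border <- 0L
  if (params$exclude_border) {
    border_labels <- unique(c(labels[1L, ], labels[nrow(labels), ],
                              labels[, 1L], labels[, ncol(labels)]))
    border_labels <- border_labels[border_labels > 0L]
    if (length(border_labels)) {
      labels[labels %in% border_labels] <- 0L
      # relabel compactly, preserving scan order
      old <- sort(unique(labels[labels > 0L]))
      map <- integer(max(old, 0L)); map[old] <- seq_along(old)
      labels[labels > 0L] <- map[labels[labels > 0L]]
      attr(labels, "n_components") <- length(old)
      n_excluded_border <- length(border_labels)
    }
  }
  filt <- with_stage("filter_by_size",
                     filter_by_size(labels, image$pixel_size_um,
                                    params$size_filter))
  spots <- with_stage("measure_spots",
                      measure_spots(labels, image))
  spots$accepted <- spots$spot_id %in% filt$accepted
  acc_areas <- spots$area_um2[spots$accepted]
  size_stats <- if (length(acc_areas))
    list(min = min(acc_areas), max = max(acc_areas),
         mean = mean(acc_areas), median = stats::median(acc_areas))
  else list(min = NA_real_, max = NA_real_, mean = NA_real_, median = NA_real_)
  breaks <- seq(params$size_filter$min_area_um2,
                params$size_filter$max_area_um2, length.out = 21L)
  counts <- if (length(acc_areas))
    as.integer(table(cut(acc_areas, breaks, include.lowest = TRUE)))
  else integer(20L)
  structure(list(type = "SpotReport",
                 well_id = image$well_id,
                 n_labeled = n_labels(labels),
                 n_accepted = length(filt$accepted),
                 n_rejected_small = length(filt$rejected_small),
                 n_rejected_large = length(filt$rejected_large),
                 n_excluded_border = n_excluded_border,
                 size_stats = size_stats,
                 size_histogram = list(breaks = breaks, counts = counts),
                 spots = spots,
                 params = params),
            class = "SpotReport")
}

#' @export
print.SpotReport <- function(x, ...) {
  cat("SpotReport '", x$well_id, "': ", x$n_accepted, " spots accepted (",
      x$n_labeled, " labelled; ", x$n_rejected_small, " too small, ",
      x$n_rejected_large, " too large)\n", sep = "")
  if (x$n_accepted > 0)
    cat("  accepted area um^2: min ", format(x$size_stats$min, digits = 4),
        ", median ", format(x$size_stats$median, digits = 4),
        ", max ", format(x$size_stats$max, digits = 4), "\n", sep = "")
  invisible(x)
}
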