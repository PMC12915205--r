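# Synthetic ground-truth generators.
#
# Both generators are seeded and fully deterministic; they provide the
# exact answer key (spot classes and positions in 2D; cell positions and
# analytic signed distances in 3D) against which the quantification
# engines are validated. Each call uses one RNG stream derived from the
# spec's seed, so ground truth does not depend on evaluation order.

#' Specification of a synthetic ELISPOT well
#'
#' Describes the background model (level + linear gradient along x),
#' the planted objects (dark anti-aliased disks: in-range spots plus
#' small and large artifacts), optical blur and additive Gaussian noise.
#' Artifact diameters are required to lie strictly outside
#' \code{paired_filter}, and spot diameters strictly inside, so the
#' generated classes are separable by construction.
#'
#' Defaults emulate a membrane imaged at 1 um/px with spot diameters of
#' 20-60 um, a spot/noise amplitude ratio of 5, and an illumination
#' gradient of a few percent across the well. Small debris renders darker
#' than true spots (\code{artifact_small_depth_factor}), as pen marks and
#' pigment specks typically are.
#'
#' @param image_size_px \code{c(H, W)} in pixels.
#' @param pixel_size_um um per pixel.
#' @param n_spots number of in-range spots.
#' @param spot_diameter_range_um \code{c(lo, hi)} spot diameters, um.
#' @param n_artifacts_small,artifact_small_diameter_um count and diameter
#'   range of sub-threshold debris.
#' @param n_artifacts_large,artifact_large_diameter_um count and diameter
#'   range of over-sized blotches.
#' @param artifact_small_depth_factor intensity drop of small debris
#'   relative to \code{spot_depth} (pen marks and pigment specks are
#'   typically much darker than true spots).
#' @param artifact_large_depth_factor intensity drop of large blotches
#'   relative to \code{spot_depth}.
#' @param spot_depth intensity drop of objects below the background.
#' @param background_level background intensity.
#' @param background_gradient intensity change per pixel along x.
#' @param noise_sd additive Gaussian noise SD.
#' @param blur_sigma_um optical blur (Gaussian sigma), um.
#' @param min_separation_um minimum pairwise centre separation, um.
#' @param paired_filter the \code{SizeFilterRange} the artifact classes are
#'   constructed against.
#' @param seed RNG seed.
#' @return a \code{SyntheticWellSpec}.
#' @export
synthetic_well_spec <- function(image_size_px = c(1600, 1600),
                                pixel_size_um = 1,
                                n_spots = 50,
                                spot_diameter_range_um = c(20, 60),
                                n_artifacts_small = 5,
                                artifact_small_diameter_um = c(3.9, 4.2),
                                n_artifacts_large = 3,
                                artifact_large_diameter_um = c(90, 120),
                                artifact_small_depth_factor = 3,
                                artifact_large_depth_factor = 1,
                                spot_depth = 150,
                                background_level = 200,
                                background_gradient = 0.02,
                                noise_sd = 30,
                                blur_sigma_um = 1.5,
                                min_separation_um = 70,
                                paired_filter = size_filter_range(),
                                seed = 1) {
  area <- function(d) pi * (d / 2)^2
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 32),
            pixel_size_um > 0, n_spots >= 0,
            n_artifacts_small >= 0, n_artifacts_large >= 0,
            spot_depth > 0, artifact_small_depth_factor > 0,
            artifact_large_depth_factor > 0,
            noise_sd >= 0, blur_sigma_um >= 0,
            min_separation_um > 0, inherits(paired_filter, "SizeFilterRange"))
  if (!(area(spot_diameter_range_um[1L]) > paired_filter$min_area_um2 &&
        area(spot_diameter_range_um[2L]) < paired_filter$max_area_um2))
    stop("spot diameters must fall strictly inside the paired size filter")
  if (n_artifacts_small > 0 &&
      area(artifact_small_diameter_um[2L]) >= paired_filter$min_area_um2)
    stop("small-artifact diameters must fall strictly below the filter minimum")
  if (n_artifacts_large > 0 &&
      area(artifact_large_diameter_um[1L]) <= paired_filter$max_area_um2)
    stop("large-artifact diameters must fall strictly above the filter maximum")
  structure(as.list(environment())[c(
    "image_size_px", "pixel_size_um", "n_spots", "spot_diameter_range_um",
    "n_artifacts_small", "artifact_small_diameter_um",
    "n_artifacts_large", "artifact_large_diameter_um",
    "artifact_small_depth_factor", "artifact_large_depth_factor",
    "spot_depth", "background_level", "background_gradient", "noise_sd",
    "blur_sigma_um", "min_separation_um", "paired_filter", "seed")],
    class = "SyntheticWellSpec")
}

# Rejection-sampled centres in a rectangle (um). The required pairwise
# centre distance is the larger of min_sep and the two objects' radii plus
# a clearance, so objects can neither violate the separation rule nor
# overlap (which would merge their segmented regions).
place_centres <- function(n, lo, hi, min_sep, radii = rep(0, n),
                          clearance = 10, max_tries = 10000L) {
  pts <- matrix(numeric(0), 0L, 2L)
  out <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- c(stats::runif(1, lo[1L], hi[1L]), stats::runif(1, lo[2L], hi[2L]))
      if (!nrow(pts)) { ok <- TRUE; break }
      need <- pmax(min_sep, radii[seq_len(i - 1L)] + radii[i] + clearance)
      if (all(sqrt((pts[, 1L] - p[1L])^2 + (pts[, 2L] - p[2L])^2) >= need)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("could not place ", n, " objects with ", min_sep,
           " um separation; reduce object count or separation")
    pts <- rbind(pts, p)
    out[i, ] <- p
  }
  out
}

# Sub-pixel (4x4 supersampled) coverage of one disk, returned as a patch
# (bounding-box indices + intensity drop) so the caller can subtract it
# in place without copying the full image.
disk_patch <- function(dims, cy_um, cx_um, diameter_um, depth, pixel_size_um) {
  r_um <- diameter_um / 2
  r0 <- max(1L, floor((cy_um - r_um) / pixel_size_um))
  r1 <- min(dims[1L], ceiling((cy_um + r_um) / pixel_size_um) + 1L)
  c0 <- max(1L, floor((cx_um - r_um) / pixel_size_um))
  c1 <- min(dims[2L], ceiling((cx_um + r_um) / pixel_size_um) + 1L)
  rows <- r0:r1; cols <- c0:c1
  sub <- (seq_len(4L) - 0.5) / 4          # subpixel offsets in [0,1]
  cov <- matrix(0, length(rows), length(cols))
  for (oy in sub) for (ox in sub) {
    yy <- (rows - 1 + oy) * pixel_size_um - cy_um
    xx <- (cols - 1 + ox) * pixel_size_um - cx_um
    cov <- cov + (outer(yy^2, xx^2, "+") <= r_um^2)
  }
  list(rows = rows, cols = cols, drop = depth * cov / 16)
}

render_disk <- function(img, cy_um, cx_um, diameter_um, depth, pixel_size_um) {
  p <- disk_patch(dim(img), cy_um, cx_um, diameter_um, depth, pixel_size_um)
  img[p$rows, p$cols] <- img[p$rows, p$cols] - p$drop
  img
}

#' Generate a synthetic ELISPOT well with ground truth
#'
#' Renders the background plane plus gradient, plants dark anti-aliased
#' disks for spots and artifacts at pairwise-separated positions, applies
#' Gaussian optical blur, adds Gaussian noise, and quantises to integer
#' camera counts. Identical seeds give bit-identical images.
#'
#' @param spec a \code{SyntheticWellSpec}.
#' @return list with \code{image} (a \code{CalibratedImage2D}) and
#'   \code{truth} (a \code{GroundTruth2D}: one row per planted object with
#'   centre, diameter, nominal area and class, plus per-class totals).
#' @export
generate_well <- function(spec) {
  stopifnot(inherits(spec, "SyntheticWellSpec"))
  set.seed(spec$seed, kind = "Mersenne-Twister")
  H <- spec$image_size_px[1L]; W <- spec$image_size_px[2L]
  px <- spec$pixel_size_um
  diam <- c(if (spec$n_spots > 0)
              stats::runif(spec$n_spots, spec$spot_diameter_range_um[1L],
                           spec$spot_diameter_range_um[2L]),
            if (spec$n_artifacts_small > 0)
              stats::runif(spec$n_artifacts_small,
                           spec$artifact_small_diameter_um[1L],
                           spec$artifact_small_diameter_um[2L]),
            if (spec$n_artifacts_large > 0)
              stats::runif(spec$n_artifacts_large,
                           spec$artifact_large_diameter_um[1L],
                           spec$artifact_large_diameter_um[2L]))
  cls <- rep(c("spot", "artifact_small", "artifact_large"),
             c(spec$n_spots, spec$n_artifacts_small, spec$n_artifacts_large))
  n <- length(diam)
  margin <- (if (n) max(diam) else 0) / 2 + 3 * spec$blur_sigma_um + 2 * px
  # faint debris is kept clear of larger objects so its (non-)detection is
  # intrinsic, not an occlusion effect of a neighbour's intensity footprint
  clear_r <- diam / 2
  clear_r[cls == "artifact_small"] <- pmax(clear_r[cls == "artifact_small"], 60)
  ctr <- place_centres(n, c(margin, margin),
                       c(H * px - margin, W * px - margin),
                       spec$min_separation_um, radii = clear_r)
  img <- matrix(spec$background_level, H, W) +
    matrix(spec$background_gradient * (seq_len(W) - (W + 1) / 2),
           H, W, byrow = TRUE)
  depth_i <- spec$spot_depth *
    c(spot = 1, artifact_small = spec$artifact_small_depth_factor,
      artifact_large = spec$artifact_large_depth_factor)[cls]
  for (i in seq_len(n)) {
    p <- disk_patch(dim(img), ctr[i, 1L], ctr[i, 2L], diam[i], depth_i[i], px)
    img[p$rows, p$cols] <- img[p$rows, p$cols] - p$drop
  }
  if (spec$blur_sigma_um > 0) {
    k <- gaussian_kernel_1d(spec$blur_sigma_um / px)
    img <- matrix(.sep_convolve(as.numeric(img), dim(img), list(k, k)), H, W)
  }
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(H * W, sd = spec$noise_sd)
  img <- pmin(pmax(round(img), 0), 65535)
  truth <- data.frame(
    object_id = seq_len(n),
    class = cls,
    center_y_um = ctr[, 1L],
    center_x_um = ctr[, 2L],
    diameter_um = diam,
    area_um2 = pi * (diam / 2)^2)
  structure(list(
    image = calibrated_image_2d(img, pixel_size_um = px,
                                polarity = "dark_spots_on_light",
                                well_id = sprintf("synthwell-seed%d", spec$seed)),
    truth = structure(list(objects = truth,
                           totals = as.list(table(factor(cls,
                             c("spot", "artifact_small", "artifact_large")))),
                           spec = spec),
                      class = "GroundTruth2D")),
    class = "SyntheticWell")
}

#' Specification of a synthetic 3D co-culture scene
#'
#' One bright organoid body (sphere or axis-aligned ellipsoid) in the
#' organoid channel and anisotropic Gaussian T-cell blobs in the tcell
#' channel, planted at requested signed distances from the organoid
#' surface (negative = inside). Defaults follow the imaging geometry of
#' the chip chambers: anisotropic voxels (coarser z) and cell extents of
#' 5 um in XY and 10 um in Z.
#'
#' @param stack_size_vox \code{c(Z, Y, X)} voxels.
#' @param voxel_size_um \code{c(dz, dy, dx)} um.
#' @param organoid list: \code{shape} ("sphere" or "ellipsoid"),
#'   \code{semi_axes_um} (scalar radius for a sphere, \code{c(az, ay, ax)}
#'   for an ellipsoid), optional \code{center_um} (z,y,x; defaults to the
#'   stack centre).
#' @param cells_inside requested signed depths, all negative, um.
#' @param cells_outside requested distances, all positive, um.
#' @param cell_fwhm_um blob FWHM per axis \code{c(z, y, x)}, um.
#' @param cell_peak peak blob intensity above background.
#' @param organoid_level organoid intensity above background.
#' @param background background level (both channels).
#' @param noise_sd additive Gaussian noise SD (both channels).
#' @param min_cell_separation_um minimum pairwise cell distance, um.
#' @param seed RNG seed.
#' @return a \code{SyntheticSceneSpec3D}.
#' @export
synthetic_scene_spec <- function(stack_size_vox = c(70, 170, 170),
                                 voxel_size_um = c(2, 1, 1),
                                 organoid = list(shape = "sphere",
                                                 semi_axes_um = 60),
                                 cells_inside = c(-30, -15),
                                 cells_outside = c(15, 30),
                                 cell_fwhm_um = c(10, 5, 5),
                                 cell_peak = 100,
                                 organoid_level = 150,
                                 background = 20,
                                 noise_sd = 10,
                                 min_cell_separation_um = 10,
                                 seed = 1) {
  stopifnot(length(stack_size_vox) == 3L, all(stack_size_vox >= 8),
            length(voxel_size_um) == 3L, all(voxel_size_um > 0),
            is.list(organoid),
            organoid$shape %in% c("sphere", "ellipsoid"),
            all(cells_inside < 0), all(cells_outside > 0),
            length(cell_fwhm_um) == 3L, all(cell_fwhm_um > 0),
            cell_peak > 0, organoid_level > 0, noise_sd >= 0)
  semi <- organoid$semi_axes_um
  organoid$semi_axes_um <- if (length(semi) == 1L) rep(semi, 3L) else semi
  stopifnot(length(organoid$semi_axes_um) == 3L,
            all(organoid$semi_axes_um > 0))
  if (is.null(organoid$center_um))
    organoid$center_um <- stack_size_vox * voxel_size_um / 2
  inradius <- min(organoid$semi_axes_um)
  if (length(cells_inside) && min(cells_inside) <= -inradius)
    stop("requested depth ", min(cells_inside),
         " um exceeds the organoid inradius (", inradius, " um)")
  structure(as.list(environment())[c(
    "stack_size_vox", "voxel_size_um", "organoid", "cells_inside",
    "cells_outside", "cell_fwhm_um", "cell_peak", "organoid_level",
    "background", "noise_sd", "min_cell_separation_um", "seed")],
    class = "SyntheticSceneSpec3D")
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# signed distance of points (rows, (z,y,x) um) to an axis-aligned ellipsoid
# by dense surface sampling; exact for spheres.
ellipsoid_signed_distance <- function(pts, center, semi, n_samples = 200000L) {
  pts <- matrix(pts, ncol = 3L)
  if (diff(range(semi)) == 0) {            # sphere: closed form
    r <- sqrt(rowSums(sweep(pts, 2L, center)^2))
    return(r - semi[1L])
  }
  u <- matrix(stats::rnorm(3L * n_samples), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  surf <- sweep(u %*% diag(semi), 2L, center, "+")
  q <- sweep(pts, 2L, center)
  inside <- rowSums(sweep(q, 2L, semi, "/")^2) < 1
  d <- vapply(seq_len(nrow(pts)), function(i) {
    dd <- sweep(surf, 2L, pts[i, ])
    sqrt(min(rowSums(dd^2)))
  }, numeric(1))
  ifelse(inside, -d, d)
}

#' Generate a synthetic 3D co-culture scene with exact ground truth
#'
#' The organoid channel holds the filled analytic body plus noise; the
#' tcell channel holds anisotropic Gaussian blobs at positions solved so
#' that each cell's analytic signed distance to the organoid surface
#' equals the requested value (radially for a sphere, along the outward
#' surface normal for an ellipsoid). The ground truth stores the exact
#' position and the analytic signed distance of every planted cell
#' (dense-surface-sampled for ellipsoids). Identical seeds give
#' bit-identical stacks.
#'
#' @param spec a \code{SyntheticSceneSpec3D}.
#' @return list with \code{stack} (a \code{CalibratedStack3D}) and
#'   \code{truth} (data.frame: cell id, class, position um, requested and
#'   analytic signed distance um).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSceneSpec3D"))
  set.seed(spec$seed, kind = "Mersenne-Twister")
  d <- spec$stack_size_vox
  vs <- spec$voxel_size_um
  ctr <- spec$organoid$center_um
  semi <- spec$organoid$semi_axes_um
  zc <- (seq_len(d[1L]) - 0.5) * vs[1L]
  yc <- (seq_len(d[2L]) - 0.5) * vs[2L]
  xc <- (seq_len(d[3L]) - 0.5) * vs[3L]
  tz <- ((zc - ctr[1L]) / semi[1L])^2
  ty <- ((yc - ctr[2L]) / semi[2L])^2
  tx <- ((xc - ctr[3L]) / semi[3L])^2
  quad <- outer(outer(tz, ty, "+"), tx, "+")
  mask <- quad <= 1
  # plant cells at the requested signed distances
  req <- c(spec$cells_inside, spec$cells_outside)
  cls <- rep(c("inside", "outside"),
             c(length(spec$cells_inside), length(spec$cells_outside)))
  extent <- d * vs
  margin <- 3 * spec$cell_fwhm_um / 2.355
  placed <- matrix(numeric(0), 0L, 3L)
  for (i in seq_along(req)) {
    ok <- FALSE
    for (t in seq_len(10000L)) {
      u <- random_unit_vector()
      if (spec$organoid$shape == "sphere") {
        p <- ctr + (semi[1L] + req[i]) * u
      } else {
        # surface point along direction u, then offset along the normal
        s <- 1 / sqrt(sum((u / semi)^2))
        sp <- ctr + s * u
        nrm <- (sp - ctr) / semi^2
        nrm <- nrm / sqrt(sum(nrm^2))
        p <- sp + req[i] * nrm
      }
      if (any(p < margin) || any(p > extent - margin)) next
      if (nrow(placed) &&
          min(sqrt(rowSums(sweep(placed, 2L, p)^2))) <
            spec$min_cell_separation_um) next
      ok <- TRUE; break
    }
    if (!ok)
      stop("could not place cell ", i, " at signed distance ", req[i],
           " um inside the stack; enlarge the stack or relax separation")
    placed <- rbind(placed, p)
  }
  true_d <- if (nrow(placed))
    ellipsoid_signed_distance(placed, ctr, semi) else numeric(0)
  # render channels
  org <- spec$background + spec$organoid_level * mask
  tcell <- array(spec$background, dim = d)
  sig_vox <- (spec$cell_fwhm_um / (2 * sqrt(2 * log(2)))) / vs
  for (i in seq_len(nrow(placed))) {
    pv <- placed[i, ] / vs + 0.5           # position in voxel coordinates
    lo <- pmax(1L, floor(pv - 3 * sig_vox))
    hi <- pmin(d, ceiling(pv + 3 * sig_vox))
    gz <- exp(-((lo[1L]:hi[1L] - pv[1L])^2) / (2 * sig_vox[1L]^2))
    gy <- exp(-((lo[2L]:hi[2L] - pv[2L])^2) / (2 * sig_vox[2L]^2))
    gx <- exp(-((lo[3L]:hi[3L] - pv[3L])^2) / (2 * sig_vox[3L]^2))
    blob <- spec$cell_peak * outer(outer(gz, gy), gx)
    tcell[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <-
      tcell[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] + blob
  }
  if (spec$noise_sd > 0) {
    tcell <- tcell + stats::rnorm(length(tcell), sd = spec$noise_sd)
    org <- org + stats::rnorm(length(org), sd = spec$noise_sd)
  }
  tcell <- array(pmin(pmax(round(tcell), 0), 65535), dim = d)
  org <- array(pmin(pmax(round(org), 0), 65535), dim = d)
  truth <- data.frame(
    cell_id = seq_len(nrow(placed)),
    class = cls[seq_len(nrow(placed))],
    z_um = placed[, 1L], y_um = placed[, 2L], x_um = placed[, 3L],
    requested_distance_um = req[seq_len(nrow(placed))],
    true_signed_distance_um = true_d)
  structure(list(
    stack = calibrated_stack_3d(
      list(tcell = tcell, organoid = org), voxel_size_um = vs,
      chamber_id = sprintf("synthscene-seed%d", spec$seed)),
    truth = truth,
    analytic_volume_um3 = 4 / 3 * pi * prod(semi),
    spec = spec),
    class = "SyntheticScene")
}
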