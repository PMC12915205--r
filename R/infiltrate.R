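# 3D T-cell infiltration quantification.
#
# A chamber stack is reduced to (i) point detections of T-cells from the
# tcell channel, (ii) a voxel segmentation + closed surface of the organoid
# from the organoid channel, and (iii) one signed shortest distance to the
# organoid surface per cell (negative inside). Cells are then classified
# against a depth window: contact at 0 um down to 200 um deep counts as
# infiltrated by default.

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

blur_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  kernels <- lapply(sigma_vox, gaussian_kernel_1d)
  array(.sep_convolve(as.numeric(arr), d, kernels), dim = d)
}

# voxel index (1-based) containing physical coordinate um along an axis
voxel_index <- function(um, spacing, n) {
  pmin(pmax(floor(um / spacing) + 1L, 1L), n)
}

#' Detect T-cells in a 3D stack
#'
#' Anisotropic blob detection on the \code{"tcell"} channel. The expected
#' cell extents (XY diameter, Z height) set per-axis Gaussian scales
#' \code{sigma = diameter / (2 sqrt(3))} (the standard blob-scale
#' relation), converted to voxels through the stack's voxel sizes. The
#' response is a difference-of-Gaussians band-pass at that scale; local
#' maxima above the detection floor are kept, then thinned so that no two
#' detections are closer than one expected diameter along any axis
#' (ellipsoidal minimum separation, strongest response wins). Centroids
#' are refined to sub-voxel positions by an intensity-weighted mean over
#' the blob neighbourhood and reported in um.
#'
#' The floor combines the response quantile from \code{params} with a
#' robust noise guard (median + 10 MAD of the response), so a stack
#' containing only background noise yields zero detections.
#'
#' @param stack a \code{CalibratedStack3D} with a \code{"tcell"} channel.
#' @param params a \code{DetectionParams3D}.
#' @return data.frame with one row per detected cell: \code{cell_id},
#'   centroid \code{z_um,y_um,x_um}, \code{peak_intensity},
#'   \code{response}, and the detection scales \code{scale_xy_um},
#'   \code{scale_z_um}.
#' @export
detect_tcells_3d <- function(stack, params = detection_params_3d()) {
  validate_calibration(stack)
  stopifnot(inherits(params, "DetectionParams3D"))
  vol <- get_channel(stack, "tcell")
  vs <- stack$voxel_size_um           # (dz, dy, dx)
  d <- dim(vol)
  sigma_um <- c(params$z_height_um, params$xy_diameter_um,
                params$xy_diameter_um) / (2 * sqrt(3))
  sigma_vox <- sigma_um / vs
  if (d[1L] * vs[1L] < params$z_height_um) {
    warning("stack depth ", d[1L] * vs[1L], " um is thinner than z_height_um = ",
            params$z_height_um, " um; detecting in-plane only")
    sigma_vox[1L] <- 0
  }
  s1 <- blur_3d(vol, sigma_vox)
  s2 <- blur_3d(vol, 1.6 * sigma_vox)
  resp <- s1 - s2
  floor_val <- max(stats::quantile(resp, params$min_intensity_quantile,
                                   names = FALSE),
                   stats::median(resp) + 10 * stats::mad(resp))
  cand <- which(.local_maxima(as.numeric(resp), d) & resp > floor_val)
  empty <- data.frame(cell_id = integer(0), z_um = numeric(0),
                      y_um = numeric(0), x_um = numeric(0),
                      peak_intensity = numeric(0), response = numeric(0),
                      scale_xy_um = numeric(0), scale_z_um = numeric(0))
  if (!length(cand)) return(empty)
  iz <- ((cand - 1L) %% d[1L]) + 1L
  iy <- (((cand - 1L) %/% d[1L]) %% d[2L]) + 1L
  ix <- ((cand - 1L) %/% (d[1L] * d[2L])) + 1L
  pos_um <- cbind((iz - 0.5) * vs[1L], (iy - 0.5) * vs[2L], (ix - 0.5) * vs[3L])
  rv <- resp[cand]
  ord <- order(-rv, cand)              # strongest first, index-stable ties
  sep <- c(params$z_height_um, params$xy_diameter_um, params$xy_diameter_um)
  keep <- logical(length(cand))
  kept_pos <- matrix(numeric(0), 0L, 3L)
  for (i in ord) {
    p <- pos_um[i, ]
    if (nrow(kept_pos)) {
      q <- sweep(kept_pos, 2L, p)
      if (any(rowSums(sweep(q, 2L, sep, "/")^2) < 1)) next
    }
    keep[i] <- TRUE
    kept_pos <- rbind(kept_pos, p)
  }
  sel <- which(keep)
  sel <- sel[order(cand[sel])]         # deterministic output order
  # sub-voxel refinement: intensity-weighted centroid over +-2 sigma
  rad <- pmax(1L, ceiling(2 * pmax(sigma_vox, 0.5)))
  out <- lapply(sel, function(i) {
    lo <- pmax(c(iz[i], iy[i], ix[i]) - rad, 1L)
    hi <- pmin(c(iz[i], iy[i], ix[i]) + rad, d)
    sub <- vol[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
    w <- pmax(sub - min(sub), 0)
    sw <- sum(w)
    g <- expand.grid(z = lo[1L]:hi[1L], y = lo[2L]:hi[2L], x = lo[3L]:hi[3L])
    if (sw > 0) {
      c(sum(g$z * w) / sw, sum(g$y * w) / sw, sum(g$x * w) / sw)
    } else c(iz[i], iy[i], ix[i])
  })
  ctr <- do.call(rbind, out)
  data.frame(cell_id = seq_along(sel),
             z_um = (ctr[, 1L] - 0.5) * vs[1L],
             y_um = (ctr[, 2L] - 0.5) * vs[2L],
             x_um = (ctr[, 3L] - 0.5) * vs[3L],
             peak_intensity = vol[cand[sel]],
             response = resp[cand[sel]],
             scale_xy_um = params$xy_diameter_um,
             scale_z_um = params$z_height_um)
}

# Otsu's threshold on a 256-bin histogram of arbitrary-range data.
otsu_threshold <- function(x, levels = 256L) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("cannot threshold a constant channel")
  h <- tabulate(pmin(as.integer((x - lo) / (hi - lo) * levels) + 1L, levels),
                nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  lo + k / levels * (hi - lo)
}

# Closed triangulated surface at the voxel-mask boundary: two triangles per
# exposed voxel face, outward winding. Vertices are voxel-corner positions
# in um, columns (x, y, z). Its enclosed volume equals the voxel volume
# exactly (both count the same voxels).
boundary_mesh <- function(mask, voxel_size_um) {
  d <- dim(mask)
  vs <- voxel_size_um                   # (dz, dy, dx)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- mask
  idx <- which(pad)
  pd <- d + 2L
  iz <- ((idx - 1L) %% pd[1L]) + 1L
  iy <- (((idx - 1L) %/% pd[1L]) %% pd[2L]) + 1L
  ix <- ((idx - 1L) %/% (pd[1L] * pd[2L])) + 1L
  shift_idx <- function(dz, dy, dx)
    (iz + dz - 1L) + (iy + dy - 1L) * pd[1L] + (ix + dx - 1L) * pd[1L] * pd[2L] + 1L
  verts <- list(); faces <- list(); nv <- 0L
  # voxel (iz,iy,ix) in padded coords -> physical corner span
  z0 <- (iz - 2L) * vs[1L]; z1 <- z0 + vs[1L]
  y0 <- (iy - 2L) * vs[2L]; y1 <- y0 + vs[2L]
  x0 <- (ix - 2L) * vs[3L]; x1 <- x0 + vs[3L]
  emit <- function(exposed, corners) {
    # corners: list of 4 corner matrices (x,y,z), counter-clockwise seen
    # from outside -> two outward triangles (1,2,3) and (1,3,4)
    n <- sum(exposed)
    if (!n) return(invisible(NULL))
    cs <- lapply(corners, function(f) f(exposed))
    v <- do.call(rbind, cs)                       # 4n x 3, grouped by corner
    base <- nv + matrix(seq_len(4L * n), nrow = n) # corner j -> col j
    tri <- rbind(cbind(base[, 1L], base[, 2L], base[, 3L]),
                 cbind(base[, 1L], base[, 3L], base[, 4L]))
    verts[[length(verts) + 1L]] <<- v
    faces[[length(faces) + 1L]] <<- tri
    nv <<- nv + 4L * n
    invisible(NULL)
  }
  # +x face (outward normal +x): CCW from +x: (x1,y0,z0),(x1,y1,z0),(x1,y1,z1),(x1,y0,z1)
  e <- !pad[shift_idx(0L, 0L, 1L)]
  emit(e, list(function(s) cbind(x1[s], y0[s], z0[s]),
               function(s) cbind(x1[s], y1[s], z0[s]),
               function(s) cbind(x1[s], y1[s], z1[s]),
               function(s) cbind(x1[s], y0[s], z1[s])))
  # -x face
  e <- !pad[shift_idx(0L, 0L, -1L)]
  emit(e, list(function(s) cbind(x0[s], y0[s], z0[s]),
               function(s) cbind(x0[s], y0[s], z1[s]),
               function(s) cbind(x0[s], y1[s], z1[s]),
               function(s) cbind(x0[s], y1[s], z0[s])))
  # +y face
  e <- !pad[shift_idx(0L, 1L, 0L)]
  emit(e, list(function(s) cbind(x0[s], y1[s], z0[s]),
               function(s) cbind(x0[s], y1[s], z1[s]),
               function(s) cbind(x1[s], y1[s], z1[s]),
               function(s) cbind(x1[s], y1[s], z0[s])))
  # -y face
  e <- !pad[shift_idx(0L, -1L, 0L)]
  emit(e, list(function(s) cbind(x0[s], y0[s], z0[s]),
               function(s) cbind(x1[s], y0[s], z0[s]),
               function(s) cbind(x1[s], y0[s], z1[s]),
               function(s) cbind(x0[s], y0[s], z1[s])))
  # +z face
  e <- !pad[shift_idx(1L, 0L, 0L)]
  emit(e, list(function(s) cbind(x0[s], y0[s], z1[s]),
               function(s) cbind(x1[s], y0[s], z1[s]),
               function(s) cbind(x1[s], y1[s], z1[s]),
               function(s) cbind(x0[s], y1[s], z1[s])))
  # -z face
  e <- !pad[shift_idx(-1L, 0L, 0L)]
  emit(e, list(function(s) cbind(x0[s], y0[s], z0[s]),
               function(s) cbind(x0[s], y1[s], z0[s]),
               function(s) cbind(x1[s], y1[s], z0[s]),
               function(s) cbind(x1[s], y0[s], z0[s])))
  list(vertices = do.call(rbind, verts), faces = do.call(rbind, faces))
}

#' Enclosed volume of a closed triangle mesh
#'
#' Signed-tetrahedron (divergence theorem) volume; absolute value is
#' returned, so winding orientation only needs to be consistent.
#'
#' @param mesh list with \code{vertices} (n x 3, um) and \code{faces}
#'   (m x 3 vertex indices).
#' @return volume in um^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  cross <- cbind(b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L],
                 b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L],
                 b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  abs(sum(a * cross) / 6)
}

#' Segment the organoid and measure its volume
#'
#' Binarises the \code{"organoid"} channel (Otsu by default, or a fixed
#' threshold), keeps the largest 26-connected body, fills fully internal
#' cavities, and extracts a closed triangulated surface at the mask
#' boundary. Volume is by voxel counting; the mesh encloses the identical
#' voxel set, so mesh volume and voxel volume agree exactly.
#'
#' @param stack a \code{CalibratedStack3D} with an \code{"organoid"} channel.
#' @param threshold_method \code{"otsu"} or \code{"fixed"}.
#' @param fixed_value threshold when \code{threshold_method = "fixed"}.
#' @return an \code{OrganoidSegmentation}: \code{mask} (3D logical),
#'   \code{surface_mesh}, \code{volume_um3}, \code{threshold_used},
#'   \code{voxel_size_um}.
#' @export
segment_organoid <- function(stack, threshold_method = c("otsu", "fixed"),
                             fixed_value = NULL) {
  validate_calibration(stack)
  threshold_method <- match.arg(threshold_method)
  ch <- get_channel(stack, "organoid")
  thr <- switch(threshold_method,
    otsu = otsu_threshold(as.numeric(ch)),
    fixed = {
      if (is.null(fixed_value)) stop("fixed threshold requires fixed_value")
      fixed_value
    })
  mask <- ch > thr
  if (!any(mask))
    stop("no organoid found: threshold ", format(thr),
         " leaves an empty mask in chamber '", stack$chamber_id, "'")
  d <- dim(mask)
  lab <- .cc_label(as.logical(mask), d, 26L)
  k <- attr(lab, "n_components")
  if (k > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = k)
    mask <- array(lab == which.max(sizes), dim = d)
  }
  # fill internal cavities: background components not reaching the border
  bg_lab <- array(.cc_label(as.logical(!mask), d, 6L), dim = d)
  border_ids <- unique(c(bg_lab[c(1L, d[1L]), , ], bg_lab[, c(1L, d[2L]), ],
                         bg_lab[, , c(1L, d[3L])]))
  holes <- bg_lab > 0L & !(bg_lab %in% border_ids)
  mask[holes] <- TRUE
  vs <- stack$voxel_size_um
  structure(list(mask = mask,
                 surface_mesh = boundary_mesh(mask, vs),
                 volume_um3 = sum(mask) * prod(vs),
                 threshold_used = thr,
                 threshold_method = threshold_method,
                 voxel_size_um = vs,
                 chamber_id = stack$chamber_id),
            class = "OrganoidSegmentation")
}

#' @export
print.OrganoidSegmentation <- function(x, ...) {
  cat("OrganoidSegmentation '", x$chamber_id, "': volume ",
      format(x$volume_um3, big.mark = ","), " um^3 (threshold ",
      format(x$threshold_used, digits = 4), ", ", x$threshold_method,
      "); mesh: ", nrow(x$surface_mesh$faces), " faces\n", sep = "")
  invisible(x)
}

#' Signed shortest distance of each cell to the organoid surface
#'
#' Euclidean distance in um from each cell centroid to the nearest organoid
#' surface point, negative when the centroid lies inside the mask. Computed
#' from two anisotropy-aware exact distance transforms (to the mask and to
#' its complement) combined with signs, sampled at the voxel containing
#' each centroid; the discretisation error is below one voxel diagonal.
#'
#' An optional nominal cell radius converts centroid-to-surface distances
#' into approximate surface-to-surface distances on the outside: positive
#' distances are reduced by \code{cell_radius_um} (floored at 0 = contact).
#' Off by default, so distances are exactly comparable to geometric ground
#' truth.
#'
#' @param cells data.frame with \code{cell_id}, \code{z_um}, \code{y_um},
#'   \code{x_um} (as returned by [detect_tcells_3d()]).
#' @param seg an \code{OrganoidSegmentation}.
#' @param cell_radius_um nominal cell radius subtracted from outside
#'   distances (0 disables).
#' @return data.frame with \code{cell_id} and \code{signed_distance_um}.
#' @export
signed_distance <- function(cells, seg, cell_radius_um = 0) {
  stopifnot(inherits(seg, "OrganoidSegmentation"))
  if (!nrow(cells))
    return(data.frame(cell_id = integer(0), signed_distance_um = numeric(0)))
  mask <- seg$mask
  d <- dim(mask)
  vs <- seg$voxel_size_um
  d_out <- .edt(as.logical(mask), d, vs)    # 0 inside, dist-to-mask outside
  d_in <- .edt(!as.logical(mask), d, vs)    # 0 outside, dist-to-bg inside
  sfield <- array(d_out - d_in, dim = d)
  iz <- voxel_index(cells$z_um, vs[1L], d[1L])
  iy <- voxel_index(cells$y_um, vs[2L], d[2L])
  ix <- voxel_index(cells$x_um, vs[3L], d[3L])
  sd_um <- sfield[cbind(iz, iy, ix)]
  if (cell_radius_um > 0)
    sd_um <- ifelse(sd_um > 0, pmax(0, sd_um - cell_radius_um), sd_um)
  data.frame(cell_id = cells$cell_id, signed_distance_um = sd_um)
}

#' Classify cells against the infiltration depth window
#'
#' A cell is \code{infiltrated} when its signed distance lies inside the
#' window (inclusive at both bounds: contact at 0 um counts), \code{outside}
#' when it is above the upper bound, and \code{excluded_deep} when it is
#' below the lower bound (deeper than 200 um under the defaults, following
#' the literal depth filter). Set \code{include_deeper = TRUE} to count
#' deeper cells as infiltrated instead.
#'
#' @param distances data.frame from [signed_distance()], or a numeric
#'   vector of signed distances in um.
#' @param window a \code{DepthWindow}.
#' @param chamber_id label carried into the result.
#' @param organoid_volume_um3 organoid volume for normalisation (NA if not
#'   available).
#' @param include_deeper merge \code{excluded_deep} into infiltrated.
#' @param params parameter echo stored in the result.
#' @return an \code{InfiltrationResult} with per-cell records, counts, the
#'   infiltrated fraction, and (when the volume is known) the infiltrated
#'   count per mm^3 of organoid.
#' @export
classify_infiltration <- function(distances, window = depth_window(),
                                  chamber_id = "chamber",
                                  organoid_volume_um3 = NA_real_,
                                  include_deeper = FALSE,
                                  params = list()) {
  stopifnot(inherits(window, "DepthWindow"))
  if (is.numeric(distances))
    distances <- data.frame(cell_id = seq_along(distances),
                            signed_distance_um = distances)
  d <- distances$signed_distance_um
  cls <- ifelse(d > window$d_max_um, "outside",
                ifelse(d < window$d_min_um, "excluded_deep", "infiltrated"))
  if (include_deeper) cls[cls == "excluded_deep"] <- "infiltrated"
  records <- data.frame(cell_id = distances$cell_id,
                        signed_distance_um = d,
                        classification = cls)
  n_total <- nrow(records)
  n_inf <- sum(cls == "infiltrated")
  vol <- organoid_volume_um3
  structure(list(type = "InfiltrationResult",
                 chamber_id = chamber_id,
                 n_cells_total = n_total,
                 n_infiltrated = n_inf,
                 n_outside = sum(cls == "outside"),
                 n_excluded_deep = sum(cls == "excluded_deep"),
                 infiltrated_fraction = if (n_total > 0) n_inf / n_total else 0,
                 organoid_volume_um3 = vol,
                 infiltrated_per_mm3 = if (is.finite(vol) && vol > 0)
                   n_inf / (vol * 1e-9) else NA_real_,
                 records = records,
                 params = c(params, list(window = unclass(window),
                                         include_deeper = include_deeper))),
            class = "InfiltrationResult")
}

#' @export
print.InfiltrationResult <- function(x, ...) {
  cat("InfiltrationResult '", x$chamber_id, "': ", x$n_infiltrated, "/",
      x$n_cells_total, " cells infiltrated (fraction ",
      format(x$infiltrated_fraction, digits = 3), "); ",
      x$n_excluded_deep, " deeper than the window; organoid ",
      format(x$organoid_volume_um3, big.mark = ","), " um^3\n", sep = "")
  invisible(x)
}

#' Pool per-chamber results across replicate chips
#'
#' Summarises infiltrated counts and fractions across chips of one
#' condition as mean and SEM (sample SD / sqrt(n)). Pooling fewer than
#' \code{min_chips} chips is refused: per-condition statistics require at
#' least that many replicate chips (default 2).
#'
#' @param results list of \code{InfiltrationResult}.
#' @param min_chips minimum number of chips required.
#' @return a \code{PooledSummary}: per-chip values plus mean and SEM of
#'   \code{n_infiltrated}, \code{infiltrated_fraction} and
#'   \code{organoid_volume_um3}.
#' @export
pool_chips <- function(results, min_chips = 2) {
  if (inherits(results, "InfiltrationResult")) results <- list(results)
  n <- length(results)
  if (n < min_chips)
    stop("pooling requires a minimum of ", min_chips, " chips per condition; got ", n)
  stopifnot(all(vapply(results, inherits, logical(1), "InfiltrationResult")))
  stat <- function(v) list(values = v, mean = mean(v),
                           sem = stats::sd(v) / sqrt(length(v)))
  structure(list(type = "PooledSummary",
                 n_chips = n,
                 chamber_ids = vapply(results, `[[`, character(1), "chamber_id"),
                 n_infiltrated = stat(vapply(results, `[[`, numeric(1),
                                             "n_infiltrated")),
                 infiltrated_fraction = stat(vapply(results, `[[`, numeric(1),
                                                    "infiltrated_fraction")),
                 organoid_volume_um3 = stat(vapply(results, `[[`, numeric(1),
                                                   "organoid_volume_um3")),
                 min_chips = min_chips),
            class = "PooledSummary")
}

#' @export
print.PooledSummary <- function(x, ...) {
  cat("PooledSummary over ", x$n_chips, " chips: infiltrated ",
      format(x$n_infiltrated$mean, digits = 4), " +/- ",
      format(x$n_infiltrated$sem, digits = 4), " (mean +/- SEM)\n", sep = "")
  invisible(x)
}

#' Quantify T-cell infiltration for one chamber
#'
#' End-to-end composition: T-cell detection, organoid segmentation and
#' volumetry, signed distances, and depth-window classification, with a
#' full parameter echo in the result.
#'
#' @param stack a \code{CalibratedStack3D} with \code{"tcell"} and
#'   \code{"organoid"} channels.
#' @param detection_params a \code{DetectionParams3D}.
#' @param segmentation_params list with \code{threshold_method} and
#'   optional \code{fixed_value}, passed to [segment_organoid()].
#' @param window a \code{DepthWindow}.
#' @param cell_radius_um see [signed_distance()].
#' @param include_deeper see [classify_infiltration()].
#' @return an \code{InfiltrationResult}.
#' @export
quantify_chamber <- function(stack,
                             detection_params = detection_params_3d(),
                             segmentation_params = list(threshold_method = "otsu"),
                             window = depth_window(),
                             cell_radius_um = 0,
                             include_deeper = FALSE) {
  cells <- with_stage("detect_tcells_3d",
                      detect_tcells_3d(stack, detection_params))
  seg <- with_stage("segment_organoid",
                    do.call(segment_organoid,
                            c(list(stack), segmentation_params)))
  dists <- with_stage("signed_distance",
                      signed_distance(cells, seg, cell_radius_um))
  res <- with_stage("classify_infiltration",
                    classify_infiltration(
                      dists, window,
                      chamber_id = stack$chamber_id,
                      organoid_volume_um3 = seg$volume_um3,
                      include_deeper = include_deeper,
                      params = list(
                        detection = unclass(detection_params),
                        segmentation = c(segmentation_params,
                                         list(threshold_used = seg$threshold_used)),
                        cell_radius_um = cell_radius_um,
                        voxel_size_um = stack$voxel_size_um)))
  res$cells <- cells
  res
}
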