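# Independent oracles used across the suite. These deliberately use naive
# algorithms (queue-based flood fill, O(n^2 w^2) sliding windows) so they
# share no code path with the package implementations they check.

# Breadth-first flood-fill labelling. Seeds are taken in ascending linear
# (column-major) index order, matching the package's documented label order.
bfs_label_oracle <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue)) {
      idx <- queue[1L]; queue <- queue[-1L]
      i <- ((idx - 1L) %% nr) + 1L
      j <- ((idx - 1L) %/% nr) + 1L
      for (o in offs) {
        ii <- i + o[1L]; jj <- j + o[2L]
        if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
        nidx <- ii + (jj - 1L) * nr
        if (mask[nidx] && lab[nidx] == 0L) {
          lab[nidx] <- k
          queue <- c(queue, nidx)
        }
      }
    }
  }
  attr(lab, "n_components") <- k
  lab
}

# Direct sliding-window local mean with symmetric reflected borders.
brute_local_mean <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(r:1, 1:nr, nr:(nr - r + 1)), c(r:1, 1:nc, nc:(nc - r + 1))]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- mean(p[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

# Flood fill of the background from the border; the complement is the
# hole-filled mask.
fill_holes_oracle <- function(mask) {
  bg <- !mask
  lab <- bfs_label_oracle(bg, connectivity = 4)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg & !(lab %in% border_labels))
}

# Greedy one-to-one matching of detected centroids to planted objects
# within a radius; returns TP/FP/FN counts.
match_detections <- function(det_yx, planted_yx, tol_um) {
  if (nrow(det_yx) == 0L)
    return(list(tp = 0L, fp = 0L, fn = nrow(planted_yx)))
  if (nrow(planted_yx) == 0L)
    return(list(tp = 0L, fp = nrow(det_yx), fn = 0L))
  used <- rep(FALSE, nrow(planted_yx))
  tp <- 0L
  for (i in seq_len(nrow(det_yx))) {
    dd <- sqrt((planted_yx[, 1L] - det_yx[i, 1L])^2 +
               (planted_yx[, 2L] - det_yx[i, 2L])^2)
    dd[used] <- Inf
    j <- which.min(dd)
    if (dd[j] <= tol_um) { used[j] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = nrow(det_yx) - tp, fn = sum(!used))
}

# Small, fast well used by unit tests (not the acceptance conditions).
small_well_spec <- function(seed = 1, n_spots = 12, n_small = 2, n_large = 1) {
  synthetic_well_spec(image_size_px = c(700, 700), n_spots = n_spots,
                      n_artifacts_small = n_small, n_artifacts_large = n_large,
                      seed = seed)
}

# Analysis parameters paired with the synthetic wells: the threshold offset
# is twice the generator's noise SD, the window radius covers the largest
# object radius so even the biggest artifact stays locally resolved, and a
# closing radius of 3 px re-attaches rim fragments of large objects whose
# neighbourhood mean is depressed in dense wells.
synthetic_well_params <- function(...)
  elispot_params(window_radius_px = 100, offset = 60,
                 closing_radius_px = 3, ...)

# Small 3D scene used by unit tests.
small_scene <- function(seed = 1, inside = c(-30, -15), outside = c(15, 30),
                        R = 60) {
  generate_scene(synthetic_scene_spec(
    stack_size_vox = c(90, 180, 180), voxel_size_um = c(2, 1, 1),
    organoid = list(shape = "sphere", semi_axes_um = R),
    cells_inside = inside, cells_outside = outside, seed = seed))
}
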