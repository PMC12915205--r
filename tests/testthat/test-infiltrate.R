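test_that("a single planted blob is detected at its position", {
  sc <- generate_scene(synthetic_scene_spec(
    stack_size_vox = c(40, 80, 80), voxel_size_um = c(2, 1, 1),
    organoid = list(shape = "sphere", semi_axes_um = 20),
    cells_inside = numeric(0), cells_outside = 25, seed = 2))
  cells <- detect_tcells_3d(sc$stack)
  expect_equal(nrow(cells), 1L)
  tr <- sc$truth
  expect_lt(abs(cells$z_um - tr$z_um), 2)   # within one voxel per axis
  expect_lt(abs(cells$y_um - tr$y_um), 1)
  expect_lt(abs(cells$x_um - tr$x_um), 1)

  # background-only stack: zero detections
  set.seed(9)
  noise <- array(round(pmax(rnorm(40 * 80 * 80, 20, 10), 0)), c(40, 80, 80))
  st <- calibrated_stack_3d(list(tcell = noise,
                                 organoid = array(20, c(40, 80, 80))),
                            c(2, 1, 1))
  expect_equal(nrow(detect_tcells_3d(st)), 0L)

  expect_error(detect_tcells_3d(
    calibrated_stack_3d(list(organoid = noise), c(2, 1, 1))), "tcell")
  expect_warning(detect_tcells_3d(
    calibrated_stack_3d(list(tcell = noise[1:3, , ]), c(2, 1, 1))),
    "thinner")
})

test_that("organoid volumes match closed forms within 5%", {
  # sphere R = 60 um in (2,1,1) voxels
  sc <- small_scene(seed = 4, inside = numeric(0), outside = numeric(0))
  seg <- segment_organoid(sc$stack)
  expect_lt(abs(seg$volume_um3 / (4 / 3 * pi * 60^3) - 1), 0.05)
  # mesh volume agrees with voxel volume (same voxel set, exactly)
  expect_equal(mesh_volume(seg$surface_mesh), seg$volume_um3)

  # ellipsoid semi-axes (40, 30, 25) um
  sce <- generate_scene(synthetic_scene_spec(
    stack_size_vox = c(60, 100, 100), voxel_size_um = c(2, 1, 1),
    organoid = list(shape = "ellipsoid", semi_axes_um = c(40, 30, 25)),
    cells_inside = numeric(0), cells_outside = numeric(0), seed = 5))
  sege <- segment_organoid(sce$stack)
  expect_lt(abs(sege$volume_um3 / (4 / 3 * pi * 40 * 30 * 25) - 1), 0.05)
})

test_that("only the largest of several bodies is kept, holes are filled", {
  d <- c(40, 90, 90)
  org <- array(20, d)
  zz <- slice.index(org, 1) * 2 - 1; yy <- slice.index(org, 2) - 0.5
  xx <- slice.index(org, 3) - 0.5
  big <- ((zz - 40)^2 + (yy - 30)^2 + (xx - 30)^2) <= 20^2
  hole <- ((zz - 40)^2 + (yy - 30)^2 + (xx - 30)^2) <= 5^2
  small <- ((zz - 40)^2 + (yy - 70)^2 + (xx - 70)^2) <= 8^2
  org[big] <- 170; org[hole] <- 20; org[small] <- 170
  st <- calibrated_stack_3d(list(tcell = array(20, d), organoid = org),
                            c(2, 1, 1))
  seg <- segment_organoid(st, threshold_method = "fixed", fixed_value = 95)
  # the small body is dropped and the internal cavity filled
  expect_lt(abs(seg$volume_um3 / (4 / 3 * pi * 20^3) - 1), 0.05)

  expect_error(segment_organoid(st, "fixed", fixed_value = 1e6),
               "no organoid found")
})

test_that("signed distances agree with the sphere closed form", {
  sc <- small_scene(seed = 6, inside = numeric(0), outside = numeric(0))
  seg <- segment_organoid(sc$stack)
  ctr <- sc$spec$organoid$center_um
  # place probe cells along an axis at radii 30, 60, 75 -> -30, 0, +15
  radii <- c(30, 60, 75)
  cells <- data.frame(cell_id = 1:3, z_um = ctr[1],
                      y_um = ctr[2], x_um = ctr[3] + radii)
  sd_ <- signed_distance(cells, seg)
  tol <- sqrt(sum(c(2, 1, 1)^2))        # one voxel diagonal
  expect_true(all(abs(sd_$signed_distance_um - c(-30, 0, 15)) <= tol))

  # sign correctness: random probes, sign matches mask membership exactly
  set.seed(11)
  n <- 1000
  d <- dim(seg$mask)
  probes <- data.frame(cell_id = seq_len(n),
                       z_um = runif(n, 1, d[1] * 2 - 1),
                       y_um = runif(n, 1, d[2] - 1),
                       x_um = runif(n, 1, d[3] - 1))
  sp <- signed_distance(probes, seg)
  iz <- pmin(pmax(floor(probes$z_um / 2) + 1, 1), d[1])
  iy <- pmin(pmax(floor(probes$y_um) + 1, 1), d[2])
  ix <- pmin(pmax(floor(probes$x_um) + 1, 1), d[3])
  inside <- seg$mask[cbind(iz, iy, ix)]
  expect_identical(sp$signed_distance_um < 0, inside)

  # optional cell-radius correction shrinks only outside distances
  sd_r <- signed_distance(cells, seg, cell_radius_um = 2.5)
  expect_equal(sd_r$signed_distance_um[1], sd_$signed_distance_um[1])
  expect_equal(sd_r$signed_distance_um[3],
               max(0, sd_$signed_distance_um[3] - 2.5))
})

test_that("depth-window classification follows the inclusive-bound rule", {
  res <- classify_infiltration(c(-250, -100, -10, 0, 15))
  expect_identical(res$records$classification,
                   c("excluded_deep", "infiltrated", "infiltrated",
                     "infiltrated", "outside"))
  expect_equal(res$n_infiltrated, 3)
  expect_equal(res$infiltrated_fraction, 3 / 5)

  # inclusive at the lower bound too
  expect_identical(
    classify_infiltration(-200)$records$classification, "infiltrated")

  # empty cell list and all-outside corner cases
  empty <- classify_infiltration(numeric(0))
  expect_equal(empty$n_cells_total, 0)
  expect_equal(empty$infiltrated_fraction, 0)
  expect_equal(classify_infiltration(rep(500, 4))$n_infiltrated, 0)

  # the escape hatch merges deep cells into infiltrated
  deep <- classify_infiltration(c(-250, -100), include_deeper = TRUE)
  expect_equal(deep$n_infiltrated, 2)

  # enlarging the window is monotone in n_infiltrated
  set.seed(3)
  dists <- runif(200, -400, 300)
  prev <- -1
  for (lo in c(-50, -100, -200, -400)) {
    n <- classify_infiltration(dists, depth_window(lo, 0))$n_infiltrated
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("pooling computes mean and SEM and enforces the chip minimum", {
  mk <- function(n_inf, n_tot = 20)
    classify_infiltration(c(rep(-10, n_inf), rep(100, n_tot - n_inf)),
                          chamber_id = paste0("chip", n_inf))
  pooled <- pool_chips(list(mk(10), mk(14)))
  expect_equal(pooled$n_infiltrated$mean, 12)
  expect_equal(pooled$n_infiltrated$sem, 2)
  expect_error(pool_chips(list(mk(10))), "minimum of 2 chips")
  same <- pool_chips(list(mk(7), mk(7), mk(7)))
  expect_equal(same$n_infiltrated$sem, 0)
})

test_that("quantify_chamber recovers planted infiltration end to end", {
  sc <- small_scene(seed = 8, inside = c(-40, -25, -10), outside = c(12, 30))
  res <- quantify_chamber(sc$stack)
  expect_equal(res$n_cells_total, 5)
  expect_equal(res$n_infiltrated, 3)
  expect_equal(res$n_outside, 2)
  expect_equal(res$infiltrated_fraction, 3 / 5)
  expect_lt(abs(res$organoid_volume_um3 / (4 / 3 * pi * 60^3) - 1), 0.05)

  # organoid-only chamber
  sc0 <- small_scene(seed = 9, inside = numeric(0), outside = numeric(0))
  res0 <- quantify_chamber(sc0$stack)
  expect_equal(res0$n_cells_total, 0)
  expect_equal(res0$infiltrated_fraction, 0)

  # determinism
  res_again <- quantify_chamber(sc$stack)
  expect_identical(res, res_again)
})
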