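test_that("adaptive threshold follows the local mean contract", {
  # constant image: no pixel is below local mean - offset (offset > 0)
  const <- calibrated_image_2d(matrix(100, 40, 40), 1)
  expect_false(any(adaptive_threshold(const, 5, offset = 10)$mask))
  # negative offset flips that
  expect_true(all(adaptive_threshold(const, 5, offset = -10)$mask))

  # dark disk on light background vs brute-force sliding-window oracle
  m <- matrix(255, 64, 64)
  yy <- row(m) - 32; xx <- col(m) - 32
  m[yy^2 + xx^2 <= 5^2] <- 0
  img <- calibrated_image_2d(m, 1)
  r <- 10
  got <- adaptive_threshold(img, r, offset = 10)$mask
  want <- m < brute_local_mean(m, r) - 10
  expect_identical(got, want)
  # mask covers the disk interior and nothing far away
  expect_true(all(got[yy^2 + xx^2 <= 4^2]))
  expect_false(any(got[yy^2 + xx^2 > 25^2]))

  # light-spot polarity flips the comparison
  img_l <- calibrated_image_2d(255 - m, 1, polarity = "light_spots_on_dark")
  expect_identical(adaptive_threshold(img_l, r, offset = 10)$mask, want)

  expect_error(adaptive_threshold(img, 64, 10), "does not fit")
})

test_that("morphological cleanup: identity, speck removal, hole filling", {
  m <- matrix(FALSE, 30, 30)
  m[10:20, 10:20] <- TRUE
  m[3, 3] <- TRUE                      # isolated speck
  expect_identical(morphological_clean(m, 0, 0, FALSE)$mask, m)  # identity
  cleaned <- morphological_clean(m, 1, 0, FALSE)$mask
  expect_false(cleaned[3, 3])
  expect_true(all(cleaned[11:19, 11:19]))

  # ring -> filled disk, area matches the border flood-fill oracle
  ring <- matrix(FALSE, 40, 40)
  yy <- row(ring) - 20; xx <- col(ring) - 20
  rr <- sqrt(yy^2 + xx^2)
  ring[rr >= 8 & rr <= 10] <- TRUE
  filled <- morphological_clean(ring, 0, 0, TRUE)$mask
  expect_identical(filled, fill_holes_oracle(ring))
  expect_true(all(filled[rr <= 8]))
})

test_that("connected components match the BFS oracle on random masks", {
  set.seed(42)
  for (rep in 1:60) {
    mask <- matrix(runif(32 * 32) < 0.4, 32, 32)
    for (conn in c(4, 8)) {
      got <- label_components(mask, conn)
      want <- bfs_label_oracle(mask, conn)
      expect_identical(unclass(got)[, ], want[, ])
      expect_identical(attr(got, "n_components"), attr(want, "n_components"))
    }
  }
  # trivial cases
  expect_identical(attr(label_components(matrix(FALSE, 5, 5)), "n_components"), 0L)
  two <- matrix(FALSE, 10, 10); two[1:3, 1:3] <- TRUE; two[6:8, 6:8] <- TRUE
  expect_identical(attr(label_components(two), "n_components"), 2L)
})

test_that("size filtration partitions inclusively and exhaustively", {
  lab <- matrix(0L, 40, 40)
  lab[1, 1:10] <- 1L          # 10 px
  lab[5:9, 1:10] <- 2L        # 50 px
  lab[15:34, 11:35] <- 3L     # 500 px
  attr(lab, "n_components") <- 3L
  f <- filter_by_size(lab, 1, size_filter_range(20, 100))
  expect_identical(f$accepted, 2L)
  expect_identical(f$rejected_small, 1L)
  expect_identical(f$rejected_large, 3L)

  # inclusive at both endpoints
  lab2 <- matrix(0L, 30, 30)
  lab2[1, 1:20] <- 1L         # exactly min area
  lab2[3:12, 1:10] <- 2L      # exactly max area
  attr(lab2, "n_components") <- 2L
  f2 <- filter_by_size(lab2, 1, size_filter_range(20, 100))
  expect_setequal(f2$accepted, c(1L, 2L))
})

test_that("spot measurements match closed forms", {
  img <- matrix(50, 40, 40)
  lab <- matrix(0L, 40, 40)
  lab[11:20, 16:25] <- 1L      # 10x10 square
  attr(lab, "n_components") <- 1L
  rec <- measure_spots(lab, img, pixel_size_um = 1)
  expect_equal(rec$area_um2, 100)
  expect_equal(rec$equivalent_diameter_um, 2 * sqrt(100 / pi))
  expect_equal(rec$mean_intensity, 50)
  expect_equal(rec$centroid_row_px, 15.5)
  expect_equal(rec$centroid_col_px, 20.5)

  # disk of radius 6 px: eccentricity ~ 0
  m2 <- matrix(0L, 41, 41)
  yy <- row(m2) - 21; xx <- col(m2) - 21
  m2[yy^2 + xx^2 <= 36] <- 1L
  lab2 <- label_components(m2 > 0)
  rec2 <- measure_spots(lab2, matrix(1, 41, 41), 1)
  expect_lt(rec2$eccentricity, 0.1)

  # physical scaling: area_um2 = area_px * pixel^2
  rec3 <- measure_spots(lab, img, pixel_size_um = 6.9)
  expect_equal(rec3$area_um2, 100 * 6.9^2)
  expect_error(measure_spots(lab, matrix(0, 10, 10), 1), "shape")
})

test_that("planted constant-intensity spots are measured faithfully", {
  gen <- generate_well(synthetic_well_spec(
    image_size_px = c(400, 400), n_spots = 3, n_artifacts_small = 0,
    n_artifacts_large = 0, noise_sd = 0, background_gradient = 0,
    blur_sigma_um = 0, seed = 11))
  rep <- count_spots(gen$image, synthetic_well_params())
  expect_equal(rep$n_accepted, 3)
  acc <- rep$spots[rep$spots$accepted, ]
  # with no blur/noise the spot interior sits exactly at bg - depth
  expect_true(all(abs(acc$mean_intensity - (200 - 150)) < 20))
  # measured area within 10% of planted disk area (nearest-centroid match)
  tr <- gen$truth$objects
  for (i in seq_len(nrow(tr))) {
    j <- which.min((acc$centroid_y_um - tr$center_y_um[i])^2 +
                   (acc$centroid_x_um - tr$center_x_um[i])^2)
    expect_lt(abs(acc$area_um2[j] / tr$area_um2[i] - 1), 0.1)
  }
})

test_that("end-to-end spot calling recovers the planted ground truth", {
  gen <- generate_well(synthetic_well_spec(
    image_size_px = c(1600, 1600), n_spots = 37,
    n_artifacts_small = 4, n_artifacts_large = 4, seed = 7))
  rep <- count_spots(gen$image, synthetic_well_params())
  expect_equal(rep$n_accepted, 37)
  expect_equal(rep$n_rejected_small + rep$n_rejected_large, 8)
  expect_equal(rep$n_labeled,
               rep$n_accepted + rep$n_rejected_small + rep$n_rejected_large)

  # blank well: background + noise only
  blank <- generate_well(synthetic_well_spec(
    image_size_px = c(700, 700), n_spots = 0, n_artifacts_small = 0,
    n_artifacts_large = 0, seed = 3))
  rep0 <- count_spots(blank$image, synthetic_well_params())
  expect_equal(rep0$n_accepted, 0)
})

test_that("spot calling is deterministic and size-filter monotone", {
  gen <- generate_well(small_well_spec(seed = 5))
  r1 <- count_spots(gen$image, synthetic_well_params())
  r2 <- count_spots(gen$image, synthetic_well_params())
  expect_identical(r1, r2)

  # raising min_area never increases the accepted count; widening the
  # range never decreases it
  prev <- Inf
  for (lo in c(10, 40, 100, 400)) {
    rep <- count_spots(gen$image, synthetic_well_params(
      size_filter = size_filter_range(lo, 4000)))
    expect_lte(rep$n_accepted, prev)
    prev <- rep$n_accepted
  }
  narrow <- count_spots(gen$image, synthetic_well_params(
    size_filter = size_filter_range(100, 1000)))
  wide <- count_spots(gen$image, synthetic_well_params(
    size_filter = size_filter_range(40, 4000)))
  expect_gte(wide$n_accepted, narrow$n_accepted)

  # count conservation on every variant
  for (r in list(r1, narrow, wide))
    expect_equal(r$n_labeled,
                 r$n_accepted + r$n_rejected_small + r$n_rejected_large)
})

test_that("stage errors carry the stage name", {
  img <- calibrated_image_2d(matrix(100, 30, 30), 1)
  expect_error(count_spots(img, elispot_params(window_radius_px = 40)),
               "adaptive_threshold")
})
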