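test_that("calibration invariants are enforced with informative errors", {
  m <- matrix(1:12, 3, 4)
  expect_s3_class(calibrated_image_2d(m, 6.9), "CalibratedImage2D")
  expect_error(calibrated_image_2d(m, 0), "pixel_size_um")
  expect_error(calibrated_image_2d(m, -1), "pixel_size_um")
  mn <- m; mn[2, 2] <- NaN
  expect_error(calibrated_image_2d(mn, 1), "non-finite")

  a <- array(1, c(4, 5, 6)); b <- array(1, c(3, 5, 6))
  expect_s3_class(
    calibrated_stack_3d(list(tcell = a, organoid = a), c(2, 1, 1)),
    "CalibratedStack3D")
  err <- tryCatch(
    calibrated_stack_3d(list(tcell = a, organoid = b), c(2, 1, 1)),
    error = conditionMessage)
  expect_match(err, "4x5x6")  # both shapes are named in the message
  expect_match(err, "3x5x6")
  expect_error(calibrated_stack_3d(list(tcell = a), c(0, 1, 1)),
               "voxel_size_um")
  st <- calibrated_stack_3d(list(tcell = a), c(2, 1, 1))
  expect_error(immunoquant:::get_channel(st, "organoid"), "organoid")
})

test_that("to_grayscale reduces RGB correctly and is idempotent", {
  m <- matrix(runif(30, 0, 255), 5, 6)
  img1 <- to_grayscale(m, pixel_size_um = 2)
  expect_identical(img1$intensities, m)
  expect_identical(to_grayscale(img1)$intensities, m)  # idempotent

  rgb_same <- array(rep(m, 3), c(5, 6, 3))
  expect_equal(to_grayscale(rgb_same, "luminance")$intensities, m)
  expect_equal(to_grayscale(rgb_same, "min")$intensities, m)

  rgb <- array(runif(5 * 6 * 3, 0, 255), c(5, 6, 3))
  gmin <- to_grayscale(rgb, "min")$intensities
  for (k in 1:3) expect_true(all(gmin <= rgb[, , k]))
  expect_equal(gmin, pmin(rgb[, , 1], rgb[, , 2], rgb[, , 3]))

  bad <- array(1, c(5, 6, 2))
  expect_error(to_grayscale(bad), "channel count")
})

test_that("TIFF round trips preserve intensities and calibration", {
  img <- calibrated_image_2d(matrix(sample(0:65535, 80 * 60, TRUE), 80, 60),
                             pixel_size_um = 6.912345,
                             polarity = "light_spots_on_dark",
                             well_id = "A3")
  f <- tempfile(fileext = ".tif")
  write_well_tiff(img, f)
  back <- read_well_image(f)
  expect_identical(back$intensities, img$intensities)  # bit-exact
  expect_lt(abs(back$pixel_size_um - img$pixel_size_um), 1e-6)
  expect_identical(back$polarity, img$polarity)
  expect_identical(back$well_id, img$well_id)

  st <- calibrated_stack_3d(
    list(tcell = array(sample(0:4095, 5 * 6 * 7, TRUE), c(5, 6, 7)),
         organoid = array(sample(0:4095, 5 * 6 * 7, TRUE), c(5, 6, 7))),
    voxel_size_um = c(2.000001, 0.999999, 1), chamber_id = "chip1-ch2")
  fs <- tempfile(fileext = ".tif")
  write_stack_tiff(st, fs)
  back3 <- read_stack_tiff(fs)
  expect_identical(back3$channels$tcell, st$channels$tcell)
  expect_identical(back3$channels$organoid, st$channels$organoid)
  expect_true(all(abs(back3$voxel_size_um - st$voxel_size_um) <= 1e-6))
  expect_identical(back3$chamber_id, st$chamber_id)
})

test_that("non-integral intensities survive the float TIFF path", {
  img <- calibrated_image_2d(matrix(rnorm(400, 100, 30), 20, 20), 1)
  f <- tempfile(fileext = ".tif")
  write_well_tiff(img, f)
  back <- read_well_image(f)
  expect_equal(back$intensities, img$intensities, tolerance = 1e-6)
})

test_that("PNG wells are read with supplied calibration", {
  m <- matrix(runif(400), 20, 20)
  f <- tempfile(fileext = ".png")
  png::writePNG(m, f)
  expect_error(read_well_image(f), "pixel_size_um")
  img <- read_well_image(f, pixel_size_um = 3)
  expect_equal(dim(img$intensities), c(20L, 20L))
  expect_equal(img$pixel_size_um, 3)
  expect_error(read_well_image(tempfile(fileext = ".png"), 1), "not found")
})
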