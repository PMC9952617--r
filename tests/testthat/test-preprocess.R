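make_shifted_cube <- function(shift, seed = 1) {
  ax <- tiny_axis()
  ph <- tiny_phantom("IBC", seed = seed)
  cube <- render_cube(ph, ax, tiny_library(), noise_sd = 8,
                      hotspot_cv = 0.25, patient_sd = 6,
                      calibration_shift = shift, seed = seed)
  silicon <- silicon_reference(cube$axis, shift = shift)
  list(cube = cube, silicon = silicon)
}

test_that("calibration recovers an injected shift and is idempotent", {
  x <- make_shifted_cube(4)
  cal <- calibrate(x$cube, x$silicon)
  expect_true(cal$metadata$calibrated)
  expect_lt(abs(cal$metadata$calibration_shift_applied - 4), 0.5)

  # identity: unshifted silicon records ~0
  x0 <- make_shifted_cube(0)
  cal0 <- calibrate(x0$cube, x0$silicon)
  expect_lt(abs(cal0$metadata$calibration_shift_applied), 0.1)

  # idempotence: re-calibrating with a silicon line on the corrected axis
  si2 <- silicon_reference(cal$axis, shift = 0)
  cal2 <- calibrate(cal, si2)
  expect_lt(abs(cal2$metadata$calibration_shift_applied), 0.1)
})

test_that("calibration rejects degenerate silicon spectra", {
  x <- make_shifted_cube(0)
  flat <- x$silicon
  flat$intensity <- rep(1, nrow(flat))
  expect_error(calibrate(x$cube, flat), "no calibration peak")
  expect_error(calibrate(x$cube, x$silicon$intensity[-1]), "axis")
})

test_that("calibration can resample onto a canonical axis", {
  x <- make_shifted_cube(1.5)
  cal <- calibrate(x$cube, x$silicon, resample_to = tiny_axis())
  expect_equal(cal$axis, tiny_axis())
  # the 722 control peak sits at its true position after resampling
  bi <- band_image(cal, 722, 0)
  i <- which.min(abs(cal$axis - 722))
  prof <- colMeans(sersstroma:::spectra_matrix(cal))
  expect_equal(which.max(prof[(i - 5):(i + 5)]), 6)
})

test_that("baseline subtraction recovers a pure baseline within 1%", {
  # oracle: the generator's stored baseline truth, default axis
  ax <- wn_axis(240, 1800, 2)
  ph <- tiny_phantom("IBC", seed = 2)
  cube <- render_cube(ph, ax, tiny_library()[0, ], noise_sd = 0,
                      hotspot_cv = 0, patient_sd = 0, seed = 3,
                      keep_truth = TRUE)
  mat <- sersstroma:::spectra_matrix(cube)[1:6, , drop = FALSE]
  corr <- subtract_baseline(mat)
  expect_lt(max(abs(corr)) / diff(range(mat)), 0.01)
})

test_that("baseline subtraction preserves a noiseless peak apex within 5%", {
  ax <- wn_axis(240, 1800, 2)
  ph <- tiny_phantom("IBC", seed = 2)
  cube <- render_cube(ph, ax, tiny_library(974, amp = 100), noise_sd = 0,
                      hotspot_cv = 0, patient_sd = 0, seed = 3)
  mat <- sersstroma:::spectra_matrix(cube)[1:6, , drop = FALSE]
  corr <- suppressWarnings(subtract_baseline(mat))
  i974 <- which.min(abs(ax - 974))
  expect_lt(max(abs(corr[, i974] - 100)) / 100, 0.05)
})

test_that("a zero spectrum stays zero under baseline subtraction", {
  z <- subtract_baseline(rep(0, 400))
  expect_equal(unname(z), rep(0, 400))
})

test_that("baseline subtraction requires calibration unless forced", {
  cube <- flat_cube()
  cube$metadata$calibrated <- FALSE
  expect_error(subtract_baseline(cube), "calibrat")
  expect_s3_class(subtract_baseline(cube, force = TRUE), "sers_cube")
  bad <- cube
  bad$intensities[1] <- NA
  expect_error(subtract_baseline(bad, force = TRUE), "finite")
})

test_that("median apex error stays under 10% at default noise", {
  # oracle: generator truth, stroma-mean spectra, default noise model
  ax <- wn_axis(240, 1800, 2)
  errs <- unlist(lapply(1:3, function(s) {
    ph <- make_phantom(c(16, 16), "IBC", seed = 1, patient_id = "P")
    cube <- render_cube(ph, ax, noise_sd = 8, hotspot_cv = 0.25,
                        patient_sd = 6, seed = 400 + s, keep_truth = TRUE)
    tr <- attr(cube, "truth")
    stroma <- as.vector(mask_labels(ph$mask)) == "cancer_stroma"
    mat <- sersstroma:::spectra_matrix(cube)
    corr <- suppressWarnings(subtract_baseline(mat[stroma, , drop = FALSE]))
    mcorr <- colMeans(corr)
    mtruth <- colMeans(tr$signal[stroma, , drop = FALSE]) + tr$offset
    idx <- vapply(default_marker_wavenumbers(),
                  function(w) which.min(abs(ax - w)), integer(1))
    abs(mcorr[idx] - mtruth[idx]) / abs(mtruth[idx])
  }))
  expect_lt(median(errs), 0.10)
})

test_that("pixel binning follows the mean convention", {
  ax <- tiny_axis()
  cube <- flat_cube(1, c(4, 4), ax)
  expect_identical(bin_pixels(cube, 1), cube)
  b2 <- bin_pixels(cube, 2)
  expect_equal(dim(b2)[1:2], c(2, 4))
  expect_true(all(b2$intensities == 1))
  expect_equal(b2$pixel_pitch, cube$pixel_pitch * 2)
  expect_error(bin_pixels(cube, 0), ">= 1")

  # brute-force oracle on a random cube, factor 5
  set.seed(9)
  arr <- array(rnorm(10 * 3 * 7), dim = c(10, 3, 7))
  rc <- sers_cube(arr, wn_axis(400, 412, 2))
  b5 <- bin_pixels(rc, 5)
  for (i in 1:2) for (j in 1:3) for (k in 1:7) {
    expect_equal(b5$intensities[i, j, k],
                 mean(arr[(5 * (i - 1) + 1):(5 * i), j, k]))
  }
})

test_that("band_image follows the closed-window sum convention", {
  ax <- tiny_axis()
  cube <- flat_cube(1, c(3, 3), ax)
  bi <- band_image(cube, 722, 5)
  # channels at 718, 720, 722, 724, 726
  expect_true(all(bi$values == 5))
  expect_error(band_image(cube, 2000, 5), "band window")

  # halfwidth 0: nearest-channel slice
  b0 <- band_image(cube, 721, 0)
  expect_equal(b0$values, cube$intensities[, , which.min(abs(ax - 721))])
})

test_that("band_image is linear and commutes with binning", {
  ax <- wn_axis(400, 440, 2)
  set.seed(4)
  x <- array(rnorm(4 * 2 * length(ax)), dim = c(4, 2, length(ax)))
  y <- array(rnorm(4 * 2 * length(ax)), dim = c(4, 2, length(ax)))
  cx <- sers_cube(x, ax); cy <- sers_cube(y, ax)
  cz <- sers_cube(2 * x + 3 * y, ax)
  expect_equal(band_image(cz, 420, 6)$values,
               2 * band_image(cx, 420, 6)$values +
                 3 * band_image(cy, 420, 6)$values)

  # bin-then-band equals band-then-bin (mean convention) -- exhaustively
  b1 <- band_image(bin_pixels(cx, 2), 420, 6)$values
  bi <- band_image(cx, 420, 6)$values
  b2 <- (bi[c(1, 3), ] + bi[c(2, 4), ]) / 2
  expect_equal(b1, b2)
})
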