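test_that("wavenumber axis is validated", {
  ax <- wn_axis(300, 1800, 2)
  expect_equal(length(ax), 751)
  expect_equal(diff(range(diff(ax))), 0)
  expect_error(wn_axis(300, 1800, -2), "step")
  expect_error(wn_axis(1800, 300, 2), "exceed")
})

test_that("phantom generation is deterministic and respects the layout", {
  p1 <- make_phantom(c(64, 64), "IBC", seed = 1)
  p2 <- make_phantom(c(64, 64), "IBC", seed = 1)
  expect_identical(p1$mask$codes, p2$mask$codes)
  expect_false(identical(
    p1$mask$codes, make_phantom(c(64, 64), "IBC", seed = 2)$mask$codes))

  pd <- make_phantom(c(64, 64), "DCIS", seed = 2)
  labs <- table(mask_labels(pd$mask))
  expect_gt(labs[["dcis"]], 0)          # nest
  expect_gt(labs[["dcis_stroma"]], 0)   # stroma
  expect_gt(labs[["fat"]], 0)           # adipose

  expect_error(make_phantom(c(4, 4), "IBC"), "8 x 8")
  expect_error(phantom_layout(nest_fraction = 0.6, fat_fraction = 0.4),
               "no stroma")
})

test_that("realized stroma fraction tracks the layout target", {
  # oracle: direct pixel count over 20 seeds
  target <- 0.5  # default layout: 1 - 0.3 - 0.15 - 0.05
  fr <- vapply(1:20, function(s) {
    ph <- make_phantom(c(32, 32), "IBC", seed = s)
    mean(mask_labels(ph$mask) == "cancer_stroma")
  }, numeric(1))
  expect_true(all(abs(fr - target) <= 0.15))
})

test_that("noiseless single-peak rendering hits the configured amplitude", {
  ax <- tiny_axis()
  lib <- tiny_library(722, amp = 100)
  ph <- tiny_phantom("IBC", seed = 1)
  cube <- render_cube(ph, ax, lib, noise_sd = 0, hotspot_cv = 0,
                      patient_sd = 0,
                      baseline = baseline_params(coef_means = rep(0, 4),
                                                 hump_amplitude = 0),
                      seed = 1)
  i722 <- which.min(abs(ax - 722))
  expect_equal(unname(cube$intensities[1, 1, i722]), 100)
})

test_that("empty peak library with no noise reproduces the baseline exactly", {
  ax <- tiny_axis()
  ph <- tiny_phantom("DCIS", seed = 2)
  cube <- render_cube(ph, ax, tiny_library()[0, ], noise_sd = 0,
                      hotspot_cv = 0, patient_sd = 0, seed = 3,
                      keep_truth = TRUE)
  mat <- sersstroma:::spectra_matrix(cube)
  expect_equal(mat, attr(cube, "truth")$baseline, tolerance = 1e-12)
})

test_that("render errors when a live peak lies off the axis", {
  lib <- tiny_library(250)  # outside 300-1200
  expect_error(
    render_cube(tiny_phantom(), tiny_axis(), lib, seed = 1),
    "250"
  )
})

test_that("IBC stroma 480 band exceeds matched DCIS renders in >= 18/20 seeds", {
  # oracle: direct band summation over stroma pixels
  ax <- tiny_axis()
  lib <- tiny_diff_library(480, hi = 100, lo = 40)
  wins <- vapply(1:20, function(s) {
    mean_band <- function(dx) {
      ph <- make_phantom(c(12, 12), dx, seed = s, patient_id = dx)
      cube <- render_cube(ph, ax, lib, noise_sd = 8, hotspot_cv = 0.25,
                          patient_sd = 6, seed = 1000 + s)
      bi <- band_image(cube, 480, 5)
      stroma <- mask_labels(ph$mask) %in% c("cancer_stroma", "dcis_stroma")
      mean(bi$values[stroma])
    }
    mean_band("IBC") > mean_band("DCIS")
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("region-mean band intensity is monotone in the configured amplitude", {
  ax <- tiny_axis()
  ph <- tiny_phantom("IBC", seed = 4)
  stroma <- mask_labels(ph$mask) == "cancer_stroma"
  vals <- vapply(c(40, 80, 160), function(a) {
    cube <- render_cube(ph, ax, tiny_library(722, amp = a), noise_sd = 0,
                        hotspot_cv = 0, patient_sd = 0, seed = 5)
    mean(band_image(cube, 722, 5)$values[stroma])
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("silicon reference apex lands where requested", {
  ax <- wn_axis(300, 1800, 2)
  si0 <- silicon_reference(ax, shift = 0)
  expect_equal(si0$wavenumber[which.max(si0$intensity)], 520)
  si4 <- silicon_reference(ax, shift = 4)
  expect_equal(si4$wavenumber[which.max(si4$intensity)], 524)
  expect_error(silicon_reference(wn_axis(600, 1800, 2), 0), "outside")
})

test_that("parabolic apex estimate resolves sub-channel shifts", {
  # oracle: dense-grid evaluation of the same line shape
  ax <- wn_axis(300, 1800, 2)
  si <- silicon_reference(ax, shift = -3.1)
  dense <- seq(500, 540, by = 0.001)
  truth <- dense[which.max(1000 * sersstroma:::lorentz(dense, 516.9, 3))]
  est <- sersstroma:::estimate_apex(si$wavenumber, si$intensity)
  expect_lt(abs(est - truth), 0.5)
})

test_that("identical cohort config and seed give a bit-identical cohort", {
  cfg <- tiny_cohort_config(seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(tiny_cohort_config(seed = 11))
  expect_identical(c1$cube[[2]]$intensities, c2$cube[[2]]$intensities)
  expect_identical(c1$mask[[3]]$codes, c2$mask[[3]]$codes)
  c3 <- simulate_cohort(tiny_cohort_config(seed = 12))
  expect_false(identical(c1$cube[[1]]$intensities, c3$cube[[1]]$intensities))
})

test_that("cohort masks live on the binned grid and cubes on the raw grid", {
  cfg <- tiny_cohort_config(seed = 3)
  cohort <- simulate_cohort(cfg)
  expect_equal(dim(cohort$cube[[1]])[1:2], c(16, 8))
  expect_equal(dim(cohort$mask[[1]]), c(8, 8))
  expect_setequal(unique(cohort$diagnosis), c("DCIS", "IBC"))
})

test_that("amplitude recovery: band image matches the windowed Lorentzian sum", {
  # noiseless; oracle = analytic sum of the profile over in-window channels
  ax <- tiny_axis()
  amp <- 100; width <- 4
  ph <- tiny_phantom("IBC", seed = 6)
  cube <- render_cube(ph, ax, tiny_library(974, amp = amp, width = width),
                      noise_sd = 0, hotspot_cv = 0, patient_sd = 0,
                      baseline = baseline_params(coef_means = rep(0, 4),
                                                 hump_amplitude = 0),
                      seed = 7)
  bi <- band_image(cube, 974, 10)
  win <- ax[abs(ax - 974) <= 10]
  analytic <- amp * sum(1 / (1 + ((win - 974) / width)^2))
  expect_equal(unname(bi$values[1, 1]), analytic, tolerance = 1e-10)
})
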