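test_that("patient_means averages exactly over the filtered records", {
  ph <- tiny_phantom("IBC", seed = 3)
  cube <- render_cube(ph, tiny_axis(), tiny_library(), noise_sd = 8, seed = 4)
  tb <- tag_spectra(cube, ph$mask)
  pm <- patient_means(list(tb), annotation_filter = "cancer_stroma")
  expect_equal(nrow(pm), 1)
  # brute-force oracle: per-channel mean over stroma records
  stroma <- tb[tb$tag == "cancer_stroma", ]
  wn_cols <- grep("^wn_", names(tb), value = TRUE)
  expect_equal(as.numeric(pm[1, wn_cols]),
               unname(colMeans(as.matrix(stroma[, wn_cols]))))
  expect_equal(pm$n_spectra, nrow(stroma))

  # single-record patient: mean is that spectrum
  one <- tb[tb$tag == "cancer_stroma", ][1, ]
  attr(one, "patient_id") <- "solo"; attr(one, "diagnosis") <- "IBC"
  class(one) <- class(tb)
  pm1 <- patient_means(list(one), annotation_filter = "cancer_stroma")
  expect_equal(as.numeric(pm1[1, wn_cols]), as.numeric(one[1, wn_cols]))
})

test_that("patients without matching annotations are dropped with a warning", {
  ph <- tiny_phantom("IBC", seed = 3)
  cube <- render_cube(ph, tiny_axis(), tiny_library(), noise_sd = 8, seed = 4)
  tb <- tag_spectra(cube, ph$mask)
  nest_only <- tb[tb$tag == "cancer_nest", ]
  attr(nest_only, "patient_id") <- "nestcase"
  attr(nest_only, "diagnosis") <- "IBC"
  class(nest_only) <- class(tb)
  expect_warning(
    pm <- patient_means(list(tb, nest_only),
                        annotation_filter = "cancer_stroma"),
    "nestcase"
  )
  expect_equal(pm$patient_id, attr(tb, "patient_id"))
})

test_that("welch_test matches the reference implementation to 1e-10", {
  set.seed(42)
  for (i in 1:1000) {
    a <- rnorm(sample(2:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:30, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    ours <- welch_test(a, b)
    ref <- t.test(a, b)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("welch_test conventions and symmetry hold", {
  x <- c(1, 2, 3)
  same <- welch_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  shifted <- welch_test(x, x + 10)
  expect_lt(shifted$p_value, 0.01)

  ab <- welch_test(c(1, 2, 4), c(5, 7, 8))
  ba <- welch_test(c(5, 7, 8), c(1, 2, 4))
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p_value, ba$p_value)

  expect_error(welch_test(1, c(1, 2)), "n >= 2")
  # zero variance in both groups, equal means: p = 1 by convention
  zz <- welch_test(c(2, 2, 2), c(2, 2))
  expect_equal(zz$p_value, 1)
})

test_that("an injected 480 band is recovered as a single I-dominant peak", {
  # generator-truth oracle: large IBC-stroma effect at 480 only
  cfg <- tiny_cohort_config(seed = 21, n_dcis = 6, n_ibc = 8)
  cohort <- simulate_cohort(cfg)
  pm <- suppressWarnings(cohort_patient_means(cohort, correct = FALSE))
  rep <- suppressWarnings(discover_differential_bands(pm))
  pk <- tidy(rep)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$wavenumber - 480), 2)
  expect_equal(pk$dominance, "I")
})

test_that("dominance follows the sign convention", {
  # DCIS > IBC effect: dominance D
  set.seed(7)
  mk_pm <- function(delta) {
    n <- c(6, 8)
    mat <- rbind(
      matrix(rnorm(n[1] * 40), n[1], 40),
      matrix(rnorm(n[2] * 40), n[2], 40)
    )
    mat[seq_len(n[1]), 18:22] <- mat[seq_len(n[1]), 18:22] + delta
    colnames(mat) <- paste0("wn_", seq(400, 478, 2))
    dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("P%02d", 1:14),
                     diagnosis = rep(c("DCIS", "IBC"), n)),
      tibble::as_tibble(mat)
    )
  }
  rep <- differential_peaks(mk_pm(8), peak_alpha = 0.001)
  expect_true(all(tidy(rep)$dominance == "D"))
  expect_gt(nrow(tidy(rep)), 0)
})

test_that("null channels are significant at about the nominal rate", {
  # type-I error simulation: iid patient matrices, no effects
  set.seed(11)
  reps <- 200
  frac <- vapply(seq_len(reps), function(r) {
    a <- matrix(rnorm(14 * 100), 14)
    b <- matrix(rnorm(32 * 100), 32)
    s <- sersstroma:::welch_stat(a, b)
    mean(s$p < 0.05)
  }, numeric(1))
  # binomial tolerance on the mean significant fraction
  expect_lt(abs(mean(frac) - 0.05), 0.005)
})

test_that("fisher_exact matches hypergeometric enumeration", {
  tab <- matrix(c(14, 0, 0, 32), 2)
  res <- fisher_exact(tab)
  expect_lt(res$p_value, 0.001)
  # oracle: sum of hypergeometric probabilities <= observed
  enum_p <- function(m) {
    rs <- rowSums(m); cs <- colSums(m)
    support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    probs <- dhyper(support, rs[1], rs[2], cs[1])
    p_obs <- dhyper(m[1, 1], rs[1], rs[2], cs[1])
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(5)
  for (i in 1:50) {
    m <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_exact(m)$p_value, enum_p(m), tolerance = 1e-9)
  }
})

test_that("fisher_exact conventions: symmetric table, metastasis margin, swaps", {
  even <- fisher_exact(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(even$p_value, 1)

  # all-M0 cohort margin: 46 = 14 + 32 vs zero M1 events
  m0 <- fisher_exact(matrix(c(14, 32, 0, 0), 2))
  expect_equal(m0$p_value, 1)

  # p invariant under row and column swaps
  set.seed(6)
  for (i in 1:25) {
    m <- matrix(rpois(4, 6), 2)
    p0 <- fisher_exact(m)$p_value
    expect_equal(fisher_exact(m[2:1, ])$p_value, p0, tolerance = 1e-12)
    expect_equal(fisher_exact(m[, 2:1])$p_value, p0, tolerance = 1e-12)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("logistic_or is calibrated under the null and detects real effects", {
  set.seed(12)
  cover <- vapply(1:50, function(r) {
    d <- data.frame(y = rep(c(0, 1), each = 100), x = rnorm(200))
    res <- logistic_or(d, "y", "x")
    res$conf_low <= 1 && 1 <= res$conf_high
  }, logical(1))
  expect_gte(mean(cover), 0.9)

  # strong positive effect: OR > 1, significant
  set.seed(13)
  x <- rnorm(120)
  y <- rbinom(120, 1, plogis(1.5 * x))
  res <- logistic_or(data.frame(y = y, x = x), "y", "x")
  expect_gt(res$or, 1)
  expect_lt(res$p_value, 0.05)
})

test_that("perfect separation is reported as an error", {
  d <- data.frame(y = rep(c(0, 1), each = 20),
                  x = rep(c(0, 1), each = 20))
  expect_error(logistic_or(d, "y", "x"), "separation")
  # collinear covariates
  d2 <- data.frame(y = rbinom(40, 1, 0.5), x = rnorm(40))
  d2$z <- d2$x * 2
  expect_error(logistic_or(d2, "y", "x", covariates = "z"), "collinear")
})

test_that("multivariable fits adjust for covariates", {
  set.seed(14)
  age <- rnorm(150, 58, 10)
  x <- rnorm(150) + 0.03 * age
  y <- rbinom(150, 1, plogis(0.8 * x - 0.02 * age))
  res <- logistic_or(data.frame(y, x, age), "y", "x", covariates = "age")
  expect_equal(res$model, c("univariable", "multivariable"))
  expect_true(all(res$or > 1))
})

test_that("triple-negative encoding handles undetermined HER2", {
  expect_equal(triple_negative(c(0, 0, 1), c(0, 0, 0), c(0, NA, NA)),
               c(1L, NA, 0L))
})
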