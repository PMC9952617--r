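test_that("stratified splits are balanced, patient-disjoint and deterministic", {
  pats <- tibble::tibble(
    patient_id = c(sprintf("D%02d", 1:14), sprintf("I%02d", 1:32)),
    diagnosis = rep(c("DCIS", "IBC"), c(14, 32))
  )
  # counting oracle over 20 seeds
  for (s in 1:20) {
    plan <- stratified_split(pats, n_sets = 4, seed = s)
    counts <- table(plan$diagnosis, plan$set)
    expect_true(all(counts["DCIS", ] %in% 3:4))
    expect_true(all(counts["IBC", ] == 8))
    expect_equal(sum(plan$role == "evaluation"),
                 sum(counts[, 4]))
    expect_false(anyDuplicated(plan$patient_id) > 0)
  }
  expect_identical(stratified_split(pats, 4, seed = 3),
                   stratified_split(pats, 4, seed = 3))

  four <- pats[c(1:2, 15:16), ]
  plan4 <- suppressWarnings(stratified_split(four, n_sets = 4, seed = 1))
  expect_true(all(table(plan4$set) == 1))
  expect_error(stratified_split(four, n_sets = 5, seed = 1), "more sets")
})

test_that("mesh features reproduce the band-window arithmetic", {
  ax <- tiny_axis()
  cube <- flat_cube(1, c(6, 6), ax)
  labs <- matrix("cancer_stroma", 6, 6)
  mesh <- stroma_mesh(annotation_mask(labs), "IBC", "P1")
  mf <- mesh_features(cube, mesh, wavenumbers = c(480, 722), halfwidth = 10)
  # 2 cm^-1 grid: 11 channels in a +/- 10 window
  expect_true(all(mf$wn_480 == 11))
  expect_true(all(mf$wn_722 == 11))
  expect_error(mesh_features(cube, mesh, wavenumbers = 2000), "outside")

  # delegation identity with band_image on a random cube
  set.seed(31)
  rc <- sers_cube(array(rnorm(6 * 6 * length(ax)), c(6, 6, length(ax))), ax)
  mf2 <- mesh_features(rc, mesh, wavenumbers = 480, halfwidth = 10)
  bi <- band_image(rc, 480, 10)$values
  expect_equal(mf2$wn_480, bi[cbind(mesh$y + 1, mesh$x + 1)])
})

test_that("cohen_kappa matches a brute-force computation", {
  expect_equal(cohen_kappa(diag(c(10, 20))), 1)
  # printed-confusion worked example
  expect_equal(round(cohen_kappa(matrix(c(2812, 13, 7, 285), 2)), 2), 0.96)

  # loop-based oracle on 1,000 random confusion matrices
  brute <- function(m) {
    n <- sum(m); po <- 0; pe <- 0
    for (i in seq_len(nrow(m))) {
      po <- po + m[i, i] / n
      ri <- 0; ci <- 0
      for (j in seq_len(ncol(m))) { ri <- ri + m[i, j]; ci <- ci + m[j, i] }
      pe <- pe + (ri / n) * (ci / n)
    }
    (po - pe) / (1 - pe)
  }
  set.seed(17)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    m <- matrix(rpois(k * k, 10) + 1, k)
    expect_equal(cohen_kappa(m), brute(m), tolerance = 1e-12)
  }

  # uniform random assignment: kappa near zero in expectation
  set.seed(18)
  ks <- vapply(1:200, function(i) {
    truth <- sample(c("DCIS", "IBC"), 400, TRUE)
    pred <- sample(c("DCIS", "IBC"), 400, TRUE)
    cohen_kappa(sersstroma:::confusion_matrix(truth, pred))
  }, numeric(1))
  expect_lt(abs(mean(ks)), 0.02)

  expect_warning(k0 <- cohen_kappa(matrix(c(10, 0, 0, 0), 2)), "degenerate")
  expect_equal(k0, 0)
  expect_error(cohen_kappa(matrix(1:6, 2)), "square")
})

test_that("separable features reach CV kappa 1 in every family", {
  feats <- synthetic_features(n_patients_per_class = 3, meshes_per_patient = 12,
                              n_features = 2, effect = 30, seed = 2)
  ms <- train_models(feats, k_folds = 3, seed = 5)
  expect_true(all(ms$cv$cv_kappa == 1))
  expect_setequal(ms$cv$model, model_families())
})

test_that("patient-permuted labels give CV kappa near zero for all families", {
  # null simulation: permute diagnosis at the patient level, 10 permutations
  feats <- synthetic_features(n_patients_per_class = 12, meshes_per_patient = 15,
                              effect = 3, seed = 3)
  pats <- dplyr::distinct(feats, patient_id, diagnosis)
  kappas <- sapply(1:10, function(r) {
    perm <- withr::with_seed(700 + r, {
      pats$diagnosis <- sample(pats$diagnosis)
      pats
    })
    pf <- dplyr::select(feats, -diagnosis) |>
      dplyr::inner_join(perm, by = "patient_id")
    grids <- lapply(default_grids(), function(g) g[1, , drop = FALSE])
    ms <- train_models(pf, k_folds = 3, grids = grids, seed = r)
    setNames(ms$cv$cv_kappa, ms$cv$model)
  })
  expect_true(all(abs(rowMeans(apply(kappas, 2, function(k) k[model_families()]))) <= 0.1))
})

test_that("evaluation enforces patient disjointness and computes metrics", {
  feats <- synthetic_features(effect = 30, seed = 4)
  pats <- unique(feats$patient_id)
  eval_ids <- c("DCIS-01", "IBC-01")
  tr <- feats[!feats$patient_id %in% eval_ids, ]
  ev <- feats[feats$patient_id %in% eval_ids, ]
  ms <- train_models(tr, algorithms = "xgboost", k_folds = 3, seed = 6)
  rep <- evaluate(ms, ev)
  expect_equal(rep$metrics$accuracy, 1)
  expect_equal(rep$metrics$kappa, 1)
  expect_error(evaluate(ms, tr[1:5, ]), "leakage")
})

test_that("evaluation metrics reproduce printed-confusion arithmetic", {
  cm <- matrix(c(2812, 13, 7, 285), 2,
               dimnames = list(c("IBC", "DCIS"), c("IBC", "DCIS")))
  m <- sersstroma:::eval_metrics(cm)
  expect_equal(round(m$kappa, 2), 0.96)
  expect_equal(round(m$accuracy, 2), 0.99)

  # balanced classes: weighted F1 equals plain macro F1
  cmb <- matrix(c(40, 10, 10, 40), 2)
  mb <- sersstroma:::eval_metrics(cmb)
  f1_class <- function(tp, fp, fn) {
    pr <- tp / (tp + fp); rc <- tp / (tp + fn)
    2 * pr * rc / (pr + rc)
  }
  macro <- mean(c(f1_class(40, 10, 10), f1_class(40, 10, 10)))
  expect_equal(mb$f1, macro)
})

test_that("permutation importance concentrates on the informative feature", {
  feats <- synthetic_features(n_patients_per_class = 4, meshes_per_patient = 25,
                              n_features = 6, informative = 1, effect = 4,
                              seed = 7)
  ms <- train_models(feats, algorithms = "xgboost", k_folds = 3, seed = 8)
  imp <- permutation_importance(ms$fits$xgboost, feats, n_repeats = 5, seed = 9)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_gt(imp$importance[imp$feature == "wn_101"], 0.5)

  # pure-noise features: no permutation moves kappa, all shares small
  noise <- synthetic_features(n_patients_per_class = 4, meshes_per_patient = 25,
                              n_features = 6, informative = 0, effect = 0,
                              seed = 10)
  msn <- train_models(noise, algorithms = "xgboost", k_folds = 3, seed = 11)
  impn <- suppressWarnings(
    permutation_importance(msn$fits$xgboost, noise, n_repeats = 5, seed = 12))
  expect_lt(max(impn$importance), 3 / 6)
})

test_that("patient aggregation reproduces the printed worked examples", {
  mk <- function(pid, n_ibc, n_dcis) {
    tibble::tibble(patient_id = pid,
                   predicted = rep(c("IBC", "DCIS"), c(n_ibc, n_dcis)))
  }
  agg <- patient_aggregate(dplyr::bind_rows(
    mk("IBC-1", 157, 4), mk("DCIS-1", 6, 138), mk("DCIS-3", 0, 98)))
  agg <- agg[match(c("IBC-1", "DCIS-1", "DCIS-3"), agg$patient_id), ]
  expect_equal(agg$ratio_ibc, c(0.975, 0.042, 0.000))
  expect_equal(agg$predicted_category, c("IBC", "DCIS", "DCIS"))
  expect_error(patient_aggregate(mk("x", 0, 0)), "aggregate")
  # exactly 0.5 is DCIS (category is IBC only above 0.5)
  half <- patient_aggregate(mk("h", 5, 5))
  expect_equal(half$predicted_category, "DCIS")
})
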