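#' Default hyperparameter grids
#'
#' Small published-default grids per algorithm family, searched by
#' cross-validated Cohen's kappa.
#'
#' @return Named list of parameter tibbles.
#' @export
default_grids <- function() {
  list(
    xgboost = tidyr::expand_grid(nrounds = 60, max_depth = c(2L, 4L), eta = 0.3),
    random_forest = tidyr::expand_grid(num_trees = 300, mtry = c(5L, 10L)),
    svm = tidyr::expand_grid(cost = c(1, 10)),
    l1_logistic = tidyr::expand_grid(lambda = c(1e-2, 1e-3)),
    knn = tidyr::expand_grid(k = c(5L, 15L)),
    naive_bayes = tibble(laplace = 0)
  )
}

#' The shipped classifier families
#'
#' @return Character vector of the six algorithm family names.
#' @export
model_families <- function() names(default_grids())

feature_cols <- function(features) {
  names(features)[is_wn_col(names(features))]
}

feature_xy <- function(features) {
  fc <- feature_cols(features)
  if (!length(fc)) data_error("no wn_* feature columns in mesh table")
  x <- as.matrix(features[, fc])
  if (anyNA(x)) data_error("missing values in mesh features")
  y <- factor(features$diagnosis, levels = c("DCIS", "IBC"))
  if (anyNA(y)) data_error("diagnosis labels outside {DCIS, IBC}")
  list(x = x, y = y)
}

# one fitted model of one family
fit_family <- function(family, x, y, params, class_weights = NULL, seed = 1) {
  fit <- switch(
    family,
    xgboost = {
      w <- if (is.null(class_weights)) rep(1, length(y)) else
        class_weights[as.character(y)]
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L, weight = w)
      with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = params$max_depth,
                      eta = params$eta, nthread = 1),
        data = dtrain, nrounds = params$nrounds, verbose = 0))
    },
    random_forest = {
      ranger::ranger(
        x = x, y = y, num.trees = params$num_trees,
        mtry = min(params$mtry, ncol(x)), seed = seed, num.threads = 1,
        class.weights = if (is.null(class_weights)) NULL else
          class_weights[levels(y)])
    },
    svm = with_seed(seed, e1071::svm(
      x = x, y = y, kernel = "radial", cost = params$cost, scale = TRUE,
      class.weights = class_weights)),
    l1_logistic = glmnet::glmnet(
      x, y, family = "binomial", alpha = 1, lambda = params$lambda,
      weights = if (is.null(class_weights)) NULL else
        unname(class_weights[as.character(y)])),
    naive_bayes = e1071::naiveBayes(
      x = as.data.frame(x), y = y, laplace = params$laplace),
    knn = {
      ctr <- colMeans(x)
      scl <- pmax(apply(x, 2, sd), 1e-12)
      list(x = scale(x, ctr, scl), y = y, k = params$k, center = ctr,
           scale = scl, seed = seed)
    },
    config_error("unknown model family '%s'", family)
  )
  structure(
    list(family = family, params = params, fit = fit,
         levels = levels(y), features = colnames(x)),
    class = "sers_fit"
  )
}

#' Predict mesh classes from a fitted model
#'
#' @param object A `sers_fit`.
#' @param newdata Mesh-feature tibble or numeric matrix with the model's
#'   feature columns.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.sers_fit <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else
    as.matrix(as_tibble(newdata)[, object$features])
  lv <- object$levels
  out <- switch(
    object$family,
    xgboost = lv[1L + as.integer(
      predict(object$fit, xgboost::xgb.DMatrix(x)) > 0.5)],
    random_forest = as.character(predict(object$fit, data = x,
                                         num.threads = 1)$predictions),
    svm = as.character(predict(object$fit, x)),
    l1_logistic = as.character(predict(object$fit, x, type = "class")),
    naive_bayes = as.character(predict(object$fit, as.data.frame(x))),
    knn = {
      xs <- scale(x, object$fit$center, object$fit$scale)
      with_seed(object$fit$seed,
                as.character(class::knn(object$fit$x, xs, object$fit$y,
                                        k = object$fit$k)))
    }
  )
  factor(out, levels = lv)
}

# patient-disjoint stratified CV folds; redraw if a fold is single-class
cv_folds <- function(features, k_folds, seed) {
  pats <- dplyr::distinct(features, .data$patient_id, .data$diagnosis)
  for (try in 0:24) {
    plan <- stratified_split(pats, n_sets = k_folds,
                             seed = child_seed(seed, 100, try), eval_set = 0)
    ok <- all(vapply(split(plan$diagnosis, plan$set),
                     function(d) length(unique(d)) == 2, logical(1)))
    if (ok) return(plan)
  }
  data_error("could not draw %d patient-disjoint folds with both classes", k_folds)
}

#' Train and select mesh classifiers
#'
#' Trains each requested algorithm family on the mesh features with
#' patient-disjoint k-fold cross-validation and grid search, selecting
#' the hyperparameter set that maximizes mean CV Cohen's kappa, then
#' refits the best configuration on the full training data.
#'
#' The six shipped families are L1-regularized logistic regression,
#' support vector machine (RBF), random forest, gradient-boosted trees,
#' k-nearest-neighbour and naive Bayes.
#'
#' @param features Mesh-feature tibble (training patients only).
#' @param algorithms Families to train; default all six.
#' @param k_folds Cross-validation folds (patient-disjoint).
#' @param grids Named list of parameter tibbles, as [default_grids()].
#' @param seed Integer seed.
#' @param class_weights `TRUE` for inverse-frequency class weights
#'   (off by default: meshes are used as-is despite class imbalance).
#' @return A `sers_model_set`: fitted models, the CV report (mean/sd
#'   kappa per family and pooled-confusion metrics at the selected
#'   parameters) and the fold plan.  `tidy()` returns the CV report.
#' @export
train_models <- function(features, algorithms = model_families(),
                         k_folds = 3, grids = default_grids(), seed = 1,
                         class_weights = FALSE) {
  features <- as_tibble(features)
  xy <- feature_xy(features)
  if (nlevels(droplevels(xy$y)) < 2) {
    data_error("training meshes must contain both classes")
  }
  bad <- setdiff(algorithms, model_families())
  if (length(bad)) config_error("unknown algorithm family '%s'", bad[1])
  folds <- cv_folds(features, k_folds, seed)
  fold_of <- setNames(folds$set, folds$patient_id)
  fidx <- unname(fold_of[features$patient_id])
  cw <- if (isTRUE(class_weights)) {
    tb <- table(xy$y)
    setNames(as.numeric(sum(tb) / (length(tb) * tb)), names(tb))
  } else NULL

  results <- lapply(algorithms, function(fam) {
    grid <- grids[[fam]]
    if (is.null(grid) || !nrow(grid)) config_error("empty grid for '%s'", fam)
    per_param <- lapply(seq_len(nrow(grid)), function(gi) {
      params <- as.list(grid[gi, ])
      fold_stats <- lapply(sort(unique(fidx)), function(f) {
        tr <- fidx != f
        fit <- fit_family(fam, xy$x[tr, , drop = FALSE], droplevels(xy$y[tr]),
                          params, cw, seed = child_seed(seed, gi, f))
        fit$features <- colnames(xy$x)
        pred <- predict(fit, xy$x[!tr, , drop = FALSE])
        cm <- confusion_matrix(xy$y[!tr], pred)
        list(kappa = cohen_kappa(cm), cm = cm)
      })
      kappas <- vapply(fold_stats, `[[`, numeric(1), "kappa")
      cm <- Reduce(`+`, lapply(fold_stats, `[[`, "cm"))
      list(params = params, mean_kappa = mean(kappas), sd_kappa = sd(kappas),
           cm = cm)
    })
    best <- which.max(vapply(per_param, `[[`, numeric(1), "mean_kappa"))
    sel <- per_param[[best]]
    fit <- fit_family(fam, xy$x, xy$y, sel$params, cw,
                      seed = child_seed(seed, 999, best))
    cv_row <- dplyr::bind_cols(
      tibble(model = fam,
             params = paste(names(sel$params), unlist(sel$params),
                            sep = "=", collapse = ", "),
             cv_kappa = sel$mean_kappa, cv_kappa_sd = sel$sd_kappa),
      eval_metrics(sel$cm)[, c("accuracy", "f1", "precision", "recall")]
    )
    list(fit = fit, cv = cv_row, cm = sel$cm)
  })

  cv <- dplyr::arrange(dplyr::bind_rows(lapply(results, `[[`, "cv")),
                       dplyr::desc(.data$cv_kappa))
  structure(
    list(fits = setNames(lapply(results, `[[`, "fit"), algorithms),
         cv = cv,
         cv_confusions = setNames(lapply(results, `[[`, "cm"), algorithms),
         folds = folds,
         train_patients = unique(features$patient_id),
         feature_names = colnames(xy$x)),
    class = "sers_model_set"
  )
}

#' @export
print.sers_model_set <- function(x, ...) {
  cat(sprintf("<sers_model_set> %d families, %d training patients\n",
              length(x$fits), length(x$train_patients)))
  print(x$cv)
  invisible(x)
}

# best family by CV kappa
best_model <- function(model_set) {
  model_set$fits[[model_set$cv$model[1]]]
}
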