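#' Evaluate models on held-out patients
#'
#' Mesh-level predictions on the evaluation set with Cohen's kappa,
#' accuracy and support-weighted F1 / precision / recall, plus the
#' confusion matrix.  Evaluation patients must be disjoint from the
#' training patients; any overlap is a hard error.
#'
#' @param object A `sers_model_set` (evaluates every family) or a single
#'   `sers_fit`.
#' @param features Mesh-feature tibble of the evaluation patients.
#' @param train_patients Training patient ids (taken from a model set
#'   automatically; required when evaluating a bare fit).
#' @return A `sers_eval_report`: `$metrics` (per model), `$confusions`
#'   and `$predictions` (per-mesh predicted classes).
#' @export
evaluate <- function(object, features, train_patients = NULL) {
  features <- as_tibble(features)
  if (inherits(object, "sers_model_set")) {
    fits <- object$fits
    train_patients <- object$train_patients
  } else if (inherits(object, "sers_fit")) {
    fits <- setNames(list(object), object$family)
  } else {
    config_error("evaluate() expects a sers_model_set or sers_fit")
  }
  overlap <- intersect(unique(features$patient_id), train_patients)
  if (length(overlap)) {
    data_error("patient-level leakage: %s in both train and evaluation sets",
               paste(overlap, collapse = ", "))
  }
  xy <- feature_xy(features)
  res <- lapply(names(fits), function(nm) {
    pred <- predict(fits[[nm]], xy$x)
    cm <- confusion_matrix(xy$y, pred)
    list(metrics = dplyr::bind_cols(tibble(model = nm), eval_metrics(cm)),
         cm = cm, pred = pred)
  })
  preds <- features[, c("patient_id", "diagnosis", "x", "y")]
  for (i in seq_along(res)) preds[[names(fits)[i]]] <- res[[i]]$pred
  structure(
    list(metrics = dplyr::arrange(dplyr::bind_rows(lapply(res, `[[`, "metrics")),
                                  dplyr::desc(.data$kappa)),
         confusions = setNames(lapply(res, `[[`, "cm"), names(fits)),
         predictions = preds,
         n_mesh = nrow(features)),
    class = "sers_eval_report"
  )
}

#' @export
print.sers_eval_report <- function(x, ...) {
  cat(sprintf("<sers_eval_report> %d evaluation meshes\n", x$n_mesh))
  print(x$metrics)
  invisible(x)
}

#' Permutation feature importance
#'
#' Mean drop in Cohen's kappa when each feature column is permuted
#' (`n_repeats` times), normalized to sum to one and ranked descending --
#' the measure behind the marker-band importance table.  Constant or
#' uninformative features get importance 0.
#'
#' @param fit A `sers_fit`.
#' @param features Mesh-feature tibble to permute over.
#' @param n_repeats Permutations per feature.
#' @param seed Integer seed.
#' @return Tibble `feature`, `wavenumber`, `mean_drop`, `importance`
#'   (unit sum), sorted by decreasing importance.
#' @export
permutation_importance <- function(fit, features, n_repeats = 10, seed = 1) {
  stopifnot(inherits(fit, "sers_fit"))
  xy <- feature_xy(features)
  if (nlevels(droplevels(xy$y)) < 2) {
    data_error("importance needs meshes from both classes")
  }
  base <- cohen_kappa(confusion_matrix(xy$y, predict(fit, xy$x)))
  drops <- vapply(seq_along(fit$features), function(j) {
    reps <- vapply(seq_len(n_repeats), function(r) {
      xp <- xy$x
      xp[, j] <- with_seed(child_seed(seed, j, r),
                           xp[sample.int(nrow(xp)), j])
      base - cohen_kappa(confusion_matrix(xy$y, predict(fit, xp)))
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  drops <- pmax(drops, 0)
  total <- sum(drops)
  imp <- if (total > 0) drops / total else rep(0, length(drops))
  if (total == 0) warn("no feature permutation changed kappa; importances all 0")
  out <- tibble(
    feature = fit$features,
    wavenumber = wn_from_col(fit$features),
    mean_drop = drops,
    importance = imp
  )
  dplyr::arrange(out, dplyr::desc(.data$importance))
}

#' Aggregate mesh predictions to the patient level
#'
#' Counts each patient's meshes predicted IBC and DCIS, their IBC ratio
#' (reported to 3 decimals), and the patient-level category: IBC if and
#' only if the ratio exceeds 0.5.
#'
#' @param mesh_predictions Tibble with `patient_id` and `predicted`
#'   (values in DCIS/IBC); an optional `diagnosis` column is carried
#'   through for comparison.
#' @return Tibble per patient: `n_pred_ibc`, `n_pred_dcis`, `ratio_ibc`,
#'   `predicted_category`.
#' @examples
#' patient_aggregate(tibble::tibble(
#'   patient_id = "P1",
#'   predicted = rep(c("IBC", "DCIS"), c(157, 4))))
#' @export
patient_aggregate <- function(mesh_predictions) {
  mp <- as_tibble(mesh_predictions)
  if (!all(c("patient_id", "predicted") %in% names(mp))) {
    config_error("mesh predictions need columns patient_id and predicted")
  }
  if (!nrow(mp)) data_error("no predicted meshes to aggregate")
  if (!all(mp$predicted %in% c("DCIS", "IBC"))) {
    data_error("predicted classes must be DCIS or IBC")
  }
  grp <- if ("diagnosis" %in% names(mp)) {
    dplyr::group_by(mp, .data$patient_id, .data$diagnosis)
  } else {
    dplyr::group_by(mp, .data$patient_id)
  }
  grp |>
    dplyr::summarise(
      n_pred_ibc = sum(.data$predicted == "IBC"),
      n_pred_dcis = sum(.data$predicted == "DCIS"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ratio_ibc = round(.data$n_pred_ibc /
                          (.data$n_pred_ibc + .data$n_pred_dcis), 3),
      predicted_category = ifelse(
        .data$n_pred_ibc / (.data$n_pred_ibc + .data$n_pred_dcis) > 0.5,
        "IBC", "DCIS")
    )
}
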