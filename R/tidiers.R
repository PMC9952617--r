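#' Tidy the differential-peak report
#'
#' @param x A `sers_diff_report`.
#' @param ... Unused.
#' @return The collapsed peak table (one row per detected band).
#' @export
tidy.sers_diff_report <- function(x, ...) x$peaks

#' @rdname tidy.sers_diff_report
#' @export
glance.sers_diff_report <- function(x, ...) {
  tibble(
    n_peaks = nrow(x$peaks),
    n_d_dominant = sum(x$peaks$dominance == "D"),
    n_i_dominant = sum(x$peaks$dominance == "I"),
    n_significant_channels = sum(x$channels$significant),
    alpha = x$alpha
  )
}

#' Tidy a trained model set
#'
#' @param x A `sers_model_set`.
#' @param ... Unused.
#' @return The cross-validation report, one row per algorithm family.
#' @export
tidy.sers_model_set <- function(x, ...) x$cv

#' @rdname tidy.sers_model_set
#' @export
glance.sers_model_set <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_families = length(x$fits),
           n_train_patients = length(x$train_patients)),
    x$cv[1, c("model", "cv_kappa")]
  )
}

#' Tidy an evaluation report
#'
#' @param x A `sers_eval_report`.
#' @param ... Unused.
#' @return Per-model evaluation metrics.
#' @export
tidy.sers_eval_report <- function(x, ...) x$metrics

#' @rdname tidy.sers_eval_report
#' @export
glance.sers_eval_report <- function(x, ...) {
  dplyr::bind_cols(tibble(n_mesh = x$n_mesh),
                   x$metrics[1, c("model", "kappa", "accuracy")])
}
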