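#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement `p_e` from the marginal products -- the model-selection and
#' evaluation criterion for mesh-level classification.
#'
#' @param confusion Nonnegative square count matrix (rows truth, columns
#'   predicted) with a positive total.
#' @return Kappa in `[-1, 1]`.  Degenerate marginals (`p_e = 1`) return 0
#'   with a warning.
#' @examples
#' cohen_kappa(matrix(c(2812, 13, 7, 285), 2))
#' @export
cohen_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) config_error("confusion matrix must be square")
  if (any(m < 0) || any(!is.finite(m))) {
    data_error("confusion entries must be nonnegative and finite")
  }
  n <- sum(m)
  if (n <= 0) data_error("confusion matrix must have a positive total")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe >= 1) {
    warn("degenerate marginals (p_e = 1); kappa defined as 0 by convention")
    return(0)
  }
  (po - pe) / (1 - pe)
}

# truth x predicted count matrix over fixed class levels
confusion_matrix <- function(truth, predicted, levels = c("DCIS", "IBC")) {
  t_f <- factor(as.character(truth), levels = levels)
  p_f <- factor(as.character(predicted), levels = levels)
  if (anyNA(t_f) || anyNA(p_f)) data_error("labels outside declared classes")
  unclass(table(truth = t_f, predicted = p_f))
}

# kappa, accuracy and support-weighted F1 / precision / recall
eval_metrics <- function(confusion) {
  m <- as.matrix(confusion)
  n <- sum(m)
  support <- rowSums(m)
  tp <- diag(m)
  prec <- ifelse(colSums(m) > 0, tp / colSums(m), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / n
  tibble(
    kappa = cohen_kappa(m),
    accuracy = sum(tp) / n,
    f1 = sum(w * f1),
    precision = sum(w * prec),
    recall = sum(w * rec)
  )
}
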