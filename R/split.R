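#' Patient-stratified split into sets
#'
#' Randomly assigns whole patients to `n_sets` class-balanced sets (class
#' counts per set within one patient of each other), so that all meshes
#' of a patient share the set and no patient-level leakage is possible.
#' One set is designated the evaluation set; the rest are training sets.
#'
#' @param patients Tibble with `patient_id` and `diagnosis` (one row per
#'   patient).
#' @param n_sets Number of sets (default 4).
#' @param seed Integer seed; identical seeds give identical plans.
#' @param eval_set Which set index is the evaluation set (`0` for none,
#'   e.g. when building cross-validation folds).
#' @return A split plan tibble: `patient_id`, `diagnosis`, `set`, `role`.
#' @examples
#' pats <- tibble::tibble(patient_id = sprintf("P%02d", 1:12),
#'                        diagnosis = rep(c("DCIS", "IBC"), c(4, 8)))
#' stratified_split(pats, n_sets = 4, seed = 1)
#' @export
stratified_split <- function(patients, n_sets = 4, seed = 1,
                             eval_set = n_sets) {
  patients <- as_tibble(patients)
  if (!all(c("patient_id", "diagnosis") %in% names(patients))) {
    config_error("patients needs columns patient_id and diagnosis")
  }
  if (anyDuplicated(patients$patient_id)) {
    data_error("duplicate patient ids in split input")
  }
  if (n_sets < 2) config_error("need at least 2 sets")
  if (n_sets > nrow(patients)) {
    config_error("more sets (%d) than patients (%d)", n_sets, nrow(patients))
  }
  small <- table(patients$diagnosis) < n_sets
  if (any(small)) {
    warn(sprintf("class(es) %s have fewer members than sets; some sets will lack them",
                 paste(names(small)[small], collapse = ", ")))
  }
  plan <- with_seed(seed, {
    parts <- lapply(split(patients, patients$diagnosis), function(g) {
      g <- g[sample.int(nrow(g)), ]
      # deal shuffled patients round-robin over a shuffled set order
      g$set <- rep(sample.int(n_sets), length.out = nrow(g))
      g
    })
    dplyr::bind_rows(parts)
  })
  plan$role <- ifelse(plan$set == eval_set, "evaluation", "train")
  dplyr::arrange(plan, .data$set, .data$diagnosis, .data$patient_id)
}
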