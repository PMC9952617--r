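# shared fixtures, generated in code

tiny_axis <- function() wn_axis(300, 1200, 2)

# a small uniform-amplitude library on a short axis
tiny_library <- function(centers = c(480, 722, 974), amp = 100, width = 4,
                         cv = 0) {
  dplyr::bind_rows(lapply(centers, function(w) {
    peak_spec(w, width = width, amplitudes = amp_ctx_all(amp),
              amplitude_cv = cv)
  }))
}

amp_ctx_all <- function(value) {
  keys <- as.vector(outer(c("DCIS", "IBC"),
                          c("nest", "stroma", "adipose", "normal"),
                          paste, sep = "."))
  stats::setNames(as.list(rep(value, length(keys))), keys)
}

# differential stroma library: one band elevated in IBC stroma
tiny_diff_library <- function(center = 480, hi = 100, lo = 40, width = 4,
                              cv = 0.1) {
  peak_spec(center, width = width,
            amplitudes = list(DCIS.stroma = lo, IBC.stroma = hi,
                              DCIS.nest = 50, IBC.nest = 50),
            amplitude_cv = cv)
}

tiny_phantom <- function(diagnosis = "IBC", seed = 1, shape = c(12, 12)) {
  make_phantom(shape, diagnosis, seed = seed,
               patient_id = paste0(diagnosis, "-T", seed))
}

# quick noiseless cube
flat_cube <- function(value = 1, shape = c(4, 4), axis = tiny_axis()) {
  sers_cube(array(value, dim = c(shape, length(axis))), axis,
            metadata = list(patient_id = "P", diagnosis = "IBC",
                            calibrated = TRUE))
}

tiny_cohort_config <- function(seed = 1, n_dcis = 2, n_ibc = 2, ...) {
  cohort_config(
    n_dcis = n_dcis, n_ibc = n_ibc, image_shape = c(16, 8), bin_factor = 2,
    axis = tiny_axis(), peak_library = tiny_diff_library(), seed = seed, ...
  )
}

# synthetic mesh features with a known class structure: informative
# features are shifted by `effect` in IBC meshes.  The informative
# features take values on a small discrete set (bounded support), so that
# with a large `effect` the two classes are separated by a gap that no
# evaluation mesh can fall into -- the exact "separable limit".
synthetic_features <- function(n_patients_per_class = 4, meshes_per_patient = 20,
                               n_features = 5, informative = 1, effect = 3,
                               seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (cl in c("DCIS", "IBC")) {
      for (p in seq_len(n_patients_per_class)) {
        pid <- sprintf("%s-%02d", cl, p)
        x <- matrix(rnorm(meshes_per_patient * n_features),
                    meshes_per_patient, n_features)
        x[, seq_len(informative)] <- sample(
          c(0, 0.5, 1), meshes_per_patient * informative, replace = TRUE)
        if (cl == "IBC") {
          x[, seq_len(informative)] <- x[, seq_len(informative)] + effect
        }
        colnames(x) <- paste0("wn_", 100 + seq_len(n_features))
        rows[[pid]] <- dplyr::bind_cols(
          tibble::tibble(patient_id = pid, diagnosis = cl,
                         x = seq_len(meshes_per_patient) - 1L, y = 0L),
          tibble::as_tibble(x)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
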