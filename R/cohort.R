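#' Cohort configuration for the synthetic generator
#'
#' The study conditions of a synthetic cohort: 14 DCIS and 32 IBC patients
#' by default (the clinical cohort's class sizes), each imaged as a raw
#' `image_shape` grid that the preprocessing stage line-bins by
#' `bin_factor` down to the mesh grid the annotation masks live on.
#'
#' Identical config and seed give a bit-identical cohort.
#'
#' @param n_dcis,n_ibc Patients per diagnosis (each >= 1).
#' @param image_shape Raw (pre-binning) grid `c(height, width)`; height
#'   must be divisible by `bin_factor`.
#' @param bin_factor Line-binning factor applied along the scan axis.
#' @param axis Wavenumber axis; the default 240-1800 cm^-1 at 2 cm^-1
#'   covers every marker band.
#' @param peak_library Peak library (long tibble).
#' @param baseline Baseline parameters from [baseline_params()].
#' @param noise_sd,hotspot_cv,patient_sd Noise model; see [render_cube()].
#' @param calibration_shift Wavenumber mislabelling in cm^-1 injected into
#'   every cube (recovered by [calibrate()]).
#' @param layout Phantom layout from [phantom_layout()].
#' @param seed Master integer seed.
#' @return A validated `sers_cohort_config` list.
#' @export
cohort_config <- function(n_dcis = 14, n_ibc = 32, image_shape = c(32, 16),
                          bin_factor = 2, axis = wn_axis(240, 1800, 2),
                          peak_library = default_peak_library(),
                          baseline = baseline_params(), noise_sd = 8,
                          hotspot_cv = 0.25, patient_sd = 6,
                          calibration_shift = 1, layout = phantom_layout(),
                          seed = 1) {
  if (n_dcis < 1 || n_ibc < 1) config_error("need >= 1 patient per diagnosis")
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2 || any(image_shape < 8)) {
    config_error("image_shape must be at least 8 x 8 pixels")
  }
  bin_factor <- as.integer(bin_factor)
  if (bin_factor < 1) config_error("bin_factor must be >= 1")
  if (image_shape[1] %% bin_factor != 0) {
    config_error("image height %d not divisible by bin_factor %d",
                 image_shape[1], bin_factor)
  }
  if (noise_sd < 0) config_error("noise_sd must be >= 0")
  check_axis(axis)
  check_peak_library(peak_library, axis)
  if (is.null(seed) || !is.finite(seed)) config_error("cohort seed is required")
  structure(
    list(n_dcis = n_dcis, n_ibc = n_ibc, image_shape = image_shape,
         bin_factor = bin_factor, axis = axis, peak_library = peak_library,
         baseline = baseline, noise_sd = noise_sd, hotspot_cv = hotspot_cv,
         patient_sd = patient_sd, calibration_shift = calibration_shift,
         layout = layout, seed = as.integer(seed)),
    class = "sers_cohort_config"
  )
}

#' Simulate an annotated synthetic cohort
#'
#' Generates one tissue phantom and raw SERS cube per patient.  The
#' annotation mask lives on the binned (mesh) grid; the raw cube repeats
#' each mesh line `bin_factor` times along the scan axis, so that
#' [bin_pixels()] recovers the mesh grid.  One master seed drives
#' independent child streams per patient and operation.
#'
#' @param config A `sers_cohort_config` from [cohort_config()].
#' @return A `sers_cohort` tibble with columns `patient_id`, `diagnosis`
#'   and list-columns `cube` (raw `sers_cube`) and `mask` (`sers_mask`),
#'   with the config and the cohort's silicon reference as attributes.
#' @examples
#' cfg <- cohort_config(n_dcis = 1, n_ibc = 1, image_shape = c(8, 8),
#'                      bin_factor = 1, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' cohort$patient_id
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sers_cohort_config")) {
    config_error("config must come from cohort_config()")
  }
  ids <- c(sprintf("DCIS-%02d", seq_len(config$n_dcis)),
           sprintf("IBC-%02d", seq_len(config$n_ibc)))
  dx <- c(rep("DCIS", config$n_dcis), rep("IBC", config$n_ibc))
  mesh_shape <- c(config$image_shape[1] %/% config$bin_factor,
                  config$image_shape[2])

  rows <- purrr::map(seq_along(ids), function(i) {
    ph <- make_phantom(mesh_shape, dx[i], layout = config$layout,
                       seed = child_seed(config$seed, i, 1),
                       patient_id = ids[i])
    # raw cube: each mesh line expands to bin_factor scan lines
    raw_mask <- ph$mask
    if (config$bin_factor > 1) {
      codes <- ph$mask$codes[rep(seq_len(mesh_shape[1]),
                                 each = config$bin_factor), , drop = FALSE]
      raw_mask <- annotation_mask(codes, ph$mask$vocabulary)
    }
    raw_ph <- structure(list(mask = raw_mask, diagnosis = ph$diagnosis,
                             patient_id = ph$patient_id),
                        class = "sers_phantom")
    cube <- render_cube(
      raw_ph, axis = config$axis, peak_library = config$peak_library,
      baseline = config$baseline, noise_sd = config$noise_sd,
      hotspot_cv = config$hotspot_cv, patient_sd = config$patient_sd,
      calibration_shift = config$calibration_shift,
      seed = child_seed(config$seed, i, 2)
    )
    list(patient_id = ids[i], diagnosis = dx[i], cube = cube, mask = ph$mask)
  })

  cohort <- tibble(
    patient_id = purrr::map_chr(rows, "patient_id"),
    diagnosis = purrr::map_chr(rows, "diagnosis"),
    cube = purrr::map(rows, "cube"),
    mask = purrr::map(rows, "mask")
  )
  attr(cohort, "config") <- config
  attr(cohort, "silicon") <- silicon_reference(
    config$axis + config$calibration_shift, shift = config$calibration_shift)
  class(cohort) <- c("sers_cohort", class(cohort))
  cohort
}

#' @export
print.sers_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<sers_cohort> %d patients (%d DCIS, %d IBC), seed %d\n",
              nrow(x), sum(x$diagnosis == "DCIS"), sum(x$diagnosis == "IBC"),
              cfg$seed))
  NextMethod()
}
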