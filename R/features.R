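#' Band-intensity features for mesh cells
#'
#' For each mesh cell (one binned stroma pixel), the accumulated band
#' intensity at each selected wavenumber over a `+/- halfwidth` window --
#' by default the 27 marker bands at +/- 10 cm^-1, the classifier's
#' feature set.
#'
#' @param cube A calibrated, baseline-corrected `sers_cube` on the mesh
#'   grid.
#' @param mesh A `sers_mesh` from [stroma_mesh()].
#' @param wavenumbers Feature band centres, cm^-1.
#' @param halfwidth Accumulation half-width, cm^-1.
#' @return A mesh-feature tibble: `patient_id`, `diagnosis`, `x`, `y` and
#'   one `wn_*` column per selected wavenumber.
#' @export
mesh_features <- function(cube, mesh, wavenumbers = default_marker_wavenumbers(),
                          halfwidth = 10) {
  stopifnot(inherits(cube, "sers_cube"))
  out_of_axis <- wavenumbers[wavenumbers < min(cube$axis) |
                             wavenumbers > max(cube$axis)]
  if (length(out_of_axis)) {
    data_error("feature wavenumber %g cm^-1 outside the cube axis",
               out_of_axis[1])
  }
  d <- dim(cube$intensities)
  px <- mesh$y + 1L + mesh$x * d[1]  # column-major pixel index
  feats <- vapply(wavenumbers, function(wn) {
    band_image(cube, wn, halfwidth)$values[px]
  }, numeric(nrow(mesh)))
  feats <- matrix(feats, nrow = nrow(mesh),
                  dimnames = list(NULL, wn_col(wavenumbers)))
  dplyr::bind_cols(
    mesh[, c("patient_id", "diagnosis", "x", "y")],
    as_tibble(feats)
  )
}

#' Mesh features for a whole processed cohort
#'
#' Preprocesses every patient of a simulated cohort (silicon calibration
#' onto the canonical axis, baseline subtraction, line binning to the
#' mesh grid), builds the stromal ROI mesh from the annotation mask, and
#' extracts the band features.
#'
#' @param cohort A `sers_cohort` from [simulate_cohort()].
#' @param wavenumbers,halfwidth Passed to [mesh_features()].
#' @param lambda Baseline-correction smoothness penalty.
#' @return A mesh-feature tibble covering all patients.
#' @export
cohort_mesh_features <- function(cohort,
                                 wavenumbers = default_marker_wavenumbers(),
                                 halfwidth = 10, lambda = 5000) {
  cfg <- attr(cohort, "config")
  silicon <- attr(cohort, "silicon")
  purrr::pmap(
    cohort[, c("patient_id", "diagnosis", "cube", "mask")],
    function(patient_id, diagnosis, cube, mask) {
      cube |>
        calibrate(silicon, resample_to = cfg$axis) |>
        bin_pixels(cfg$bin_factor) |>
        subtract_baseline(lambda = lambda) |>
        mesh_features(stroma_mesh(mask, diagnosis, patient_id),
                      wavenumbers = wavenumbers, halfwidth = halfwidth)
    }
  ) |>
    dplyr::bind_rows()
}

#' Stroma-averaged patient spectra for a whole processed cohort
#'
#' The differential-discovery input: per patient, preprocess the cube and
#' average the baseline-corrected spectra over the chosen annotation
#' classes.
#'
#' @param cohort A `sers_cohort`.
#' @param annotation_filter Tags to average over (default stromal).
#' @param correct Baseline-correct each pixel spectrum before averaging
#'   (set `FALSE` to obtain raw means, e.g. as input to
#'   [discover_differential_bands()]).
#' @param lambda Baseline-correction smoothness penalty.
#' @return Patient-spectrum tibble as from [patient_means()].
#' @export
cohort_patient_means <- function(cohort,
                                 annotation_filter = c("cancer_stroma",
                                                       "dcis_stroma"),
                                 correct = TRUE, lambda = 5000) {
  cfg <- attr(cohort, "config")
  silicon <- attr(cohort, "silicon")
  tagged <- purrr::pmap(
    cohort[, c("cube", "mask")],
    function(cube, mask) {
      cube <- cube |>
        calibrate(silicon, resample_to = cfg$axis) |>
        bin_pixels(cfg$bin_factor)
      if (correct) cube <- subtract_baseline(cube, lambda = lambda)
      tag_spectra(cube, mask)
    }
  )
  patient_means(tagged, annotation_filter = annotation_filter)
}
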