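#' Construct a hyperspectral SERS cube
#'
#' The central data carrier: a height x width x n_channels array of SERS
#' intensities (arbitrary units) on a shared wavenumber axis, with the
#' physical pixel pitch and processing metadata.
#'
#' @param intensities 3-D numeric array `[height, width, channels]`.
#' @param axis Wavenumber axis; length must equal the channel dimension.
#' @param pixel_pitch Pixel pitch in micrometres (default the 46.6 um of
#'   100-binned line-scan storage).
#' @param metadata Named list; typically `patient_id`, `diagnosis` and
#'   processing flags.
#' @return A `sers_cube`.
#' @export
sers_cube <- function(intensities, axis, pixel_pitch = 46.6, metadata = list()) {
  if (length(dim(intensities)) != 3) {
    data_error("cube intensities must be a 3-D array [height, width, channels]")
  }
  check_axis(axis)
  if (dim(intensities)[3] != length(axis)) {
    data_error("cube has %d channels but axis has %d",
               dim(intensities)[3], length(axis))
  }
  if (!all(is.finite(intensities))) data_error("cube intensities must be finite")
  if (pixel_pitch <= 0) config_error("pixel pitch must be positive")
  flags <- list(calibrated = FALSE, baseline_corrected = FALSE, bin_factor = 1L)
  structure(
    list(intensities = intensities, axis = axis, pixel_pitch = pixel_pitch,
         metadata = modifyList(flags, metadata)),
    class = "sers_cube"
  )
}

#' @export
dim.sers_cube <- function(x) dim(x$intensities)

# pixels x channels matrix view (column-major pixel order: x = col-1, y = row-1)
spectra_matrix <- function(cube) {
  d <- dim(cube$intensities)
  matrix(cube$intensities, d[1] * d[2], d[3])
}

matrix_to_cube_array <- function(mat, h, w) {
  array(mat, dim = c(h, w, ncol(mat)))
}

#' @export
print.sers_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<sers_cube> %d x %d pixels, %d channels (%.0f-%.0f cm^-1), %.3g um/px\n",
    d[1], d[2], d[3], min(x$axis), max(x$axis), x$pixel_pitch))
  md <- x$metadata
  cat(sprintf("  patient: %s  diagnosis: %s\n",
              md$patient_id %||% "?", md$diagnosis %||% "?"))
  cat(sprintf("  calibrated: %s  baseline-corrected: %s  bin factor: %d\n",
              md$calibrated, md$baseline_corrected, md$bin_factor))
  invisible(x)
}

#' Tidy a cube into long per-pixel records
#'
#' Mostly useful for small cubes and plotting; a full cube expands to
#' `height * width * channels` rows.
#'
#' @param x A `sers_cube`.
#' @param ... Unused.
#' @return Tibble with `x`, `y`, `wavenumber`, `intensity`.
#' @export
as_tibble.sers_cube <- function(x, ...) {
  d <- dim(x$intensities)
  axis <- x$axis
  vals <- as.vector(x$intensities)
  tibble(
    x = rep(rep(0:(d[2] - 1L), each = d[1]), times = d[3]),
    y = rep(rep(0:(d[1] - 1L), times = d[2]), times = d[3]),
    wavenumber = rep(axis, each = d[1] * d[2]),
    intensity = vals
  )
}

# single pixel spectrum by 0-based (x, y)
pixel_spectrum <- function(cube, x, y) cube$intensities[y + 1L, x + 1L, ]
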