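#' Construct a uniform wavenumber axis
#'
#' The fingerprint region of Raman spectra is sampled on a uniform grid of
#' wavenumber channels.  The default grid spans 300 to 1800 cm^-1 at a
#' 2 cm^-1 channel spacing, the resolution typical of a 300 grooves/mm
#' grating.
#'
#' @param start,stop Range of the axis in cm^-1.
#' @param step Channel spacing in cm^-1 (must be positive).
#' @return A numeric vector of strictly increasing, uniformly spaced channel
#'   centres.
#' @examples
#' ax <- wn_axis(300, 1800, 2)
#' length(ax)
#' @export
wn_axis <- function(start = 300, stop = 1800, step = 2) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step)) {
    config_error("wavenumber axis bounds must be numeric")
  }
  if (step <= 0) config_error("axis step must be positive, got %g", step)
  if (stop <= start) config_error("axis stop (%g) must exceed start (%g)", stop, start)
  seq(start, stop, by = step)
}

# validate an arbitrary numeric vector as a wavenumber axis
check_axis <- function(axis) {
  if (!is.numeric(axis) || length(axis) < 2) {
    config_error("axis must be a numeric vector with >= 2 channels")
  }
  d <- diff(axis)
  if (any(d <= 0)) config_error("axis must be strictly increasing")
  if (diff(range(d)) > 1e-8 * mean(d)) {
    config_error("axis must be uniformly spaced")
  }
  invisible(axis)
}

wn_step <- function(axis) mean(diff(axis))

# index of the channel centre nearest to wn
wn_nearest <- function(axis, wn) which.min(abs(axis - wn))

# indices of channels whose centres lie in the closed band window
wn_window <- function(axis, center, halfwidth) {
  which(axis >= center - halfwidth & axis <= center + halfwidth)
}
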