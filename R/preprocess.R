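#' Calibrate the wavenumber axis against the silicon phonon line
#'
#' Estimates the apex of the silicon 520 cm^-1 phonon mode by parabolic
#' interpolation over the three channels around the maximum, then shifts
#' the cube's axis so the apex sits at exactly 520 cm^-1.  The applied
#' shift is recorded in the cube metadata.
#'
#' Because each cube's estimated shift differs slightly, spectra from
#' different patients no longer share channel centres after calibration;
#' passing `resample_to` linearly interpolates every spectrum onto a
#' common axis (the usual choice is the cohort's canonical axis).
#'
#' @param cube A `sers_cube`.
#' @param silicon Silicon reference: a tibble with `wavenumber` and
#'   `intensity` sharing the cube's axis, or a bare intensity vector.
#' @param resample_to Optional target axis to interpolate onto after the
#'   shift.
#' @return The calibrated cube; `metadata$calibration_shift_applied` holds
#'   the shift that was removed.
#' @export
calibrate <- function(cube, silicon, resample_to = NULL) {
  stopifnot(inherits(cube, "sers_cube"))
  if (is.data.frame(silicon)) {
    if (!isTRUE(all.equal(silicon$wavenumber, cube$axis))) {
      data_error("silicon spectrum does not share the cube's axis")
    }
    si <- silicon$intensity
  } else {
    si <- as.numeric(silicon)
    if (length(si) != length(cube$axis)) {
      data_error("silicon spectrum does not share the cube's axis")
    }
  }
  apex <- estimate_apex(cube$axis, si)
  shift <- apex - 520
  out <- cube
  out$axis <- cube$axis - shift
  out$metadata$calibrated <- TRUE
  out$metadata$calibration_shift_applied <- shift
  if (!is.null(resample_to)) {
    check_axis(resample_to)
    mat <- spectra_matrix(out)
    res <- t(apply(mat, 1, function(s) {
      approx(out$axis, s, xout = resample_to, rule = 2)$y
    }))
    d <- dim(out$intensities)
    out$intensities <- matrix_to_cube_array(res, d[1], d[2])
    out$axis <- resample_to
  }
  out
}

# sub-channel apex by parabolic interpolation of the top 3 channels
estimate_apex <- function(wn, intensity) {
  if (!all(is.finite(intensity))) data_error("non-finite silicon spectrum")
  mx <- max(intensity)
  floor_stat <- mx - median(intensity)
  noise <- max(mad(intensity), 1e-12)
  if (floor_stat <= 0 || floor_stat < 5 * noise) {
    data_error("no calibration peak: silicon line absent or below noise floor")
  }
  if (sum(intensity == mx) > 1) data_error("silicon apex is not unique")
  i0 <- which.max(intensity)
  if (i0 == 1 || i0 == length(intensity)) {
    data_error("silicon apex at the axis edge; cannot interpolate")
  }
  ym <- intensity[i0 - 1]; y0 <- intensity[i0]; yp <- intensity[i0 + 1]
  denom <- ym - 2 * y0 + yp
  delta <- if (denom == 0) 0 else 0.5 * (ym - yp) / denom
  wn[i0] + delta * wn_step(wn)
}

#' Subtract the smooth spectral baseline
#'
#' Per-pixel baseline estimation by iteratively reweighted asymmetric
#' least squares: a Whittaker smoother with a second-order difference
#' penalty in which channels above the current fit by more than the
#' spectrum's noise threshold are down-weighted to `p` while every other
#' channel keeps weight 1.  The noise scale is estimated robustly from
#' second differences, so on noisy spectra the fit runs through the middle
#' of the noise band (no lower-envelope bias) while peak channels are
#' excluded.  The corrected spectrum is raw minus baseline: approximately
#' zero-mean off-peak with peak apex heights preserved.
#'
#' @param x A `sers_cube`, a spectra matrix (rows = spectra, columns =
#'   channels), or a single numeric spectrum.
#' @param lambda Smoothness penalty; larger is stiffer.
#' @param p Weight given to channels above the fit by more than the noise
#'   threshold (peak channels), in (0, 1).
#' @param maxit Maximum reweighting iterations.
#' @param dilate Channels by which the peak mask is widened to cover peak
#'   flanks (applied only when a nonzero noise scale is detected).
#' @param tol Relative-change convergence tolerance.
#' @param force Set `TRUE` to correct an uncalibrated cube.
#' @param keep_baseline If `TRUE`, attach the estimated baseline.
#' @return Same shape as the input, baseline-subtracted.  Non-convergence
#'   raises a warning and returns the best fit.
#' @export
subtract_baseline <- function(x, lambda = 5000, p = 0.01, maxit = 50,
                              tol = 1e-6, dilate = 6L, force = FALSE,
                              keep_baseline = FALSE) {
  UseMethod("subtract_baseline")
}

#' @export
subtract_baseline.sers_cube <- function(x, lambda = 5000, p = 0.01, maxit = 50,
                                        tol = 1e-6, dilate = 6L, force = FALSE,
                                        keep_baseline = FALSE) {
  if (!isTRUE(x$metadata$calibrated) && !force) {
    data_error("cube is not calibrated; calibrate() first or use force = TRUE")
  }
  mat <- spectra_matrix(x)
  bl <- als_baseline(mat, lambda = lambda, p = p, maxit = maxit, tol = tol,
                     dilate = dilate)
  d <- dim(x$intensities)
  out <- x
  out$intensities <- matrix_to_cube_array(mat - bl, d[1], d[2])
  out$metadata$baseline_corrected <- TRUE
  out$metadata$baseline_lambda <- lambda
  if (keep_baseline) attr(out, "baseline") <- bl
  out
}

#' @export
subtract_baseline.matrix <- function(x, lambda = 5000, p = 0.01, maxit = 50,
                                     tol = 1e-6, dilate = 6L, force = FALSE,
                                     keep_baseline = FALSE) {
  bl <- als_baseline(x, lambda = lambda, p = p, maxit = maxit, tol = tol,
                     dilate = dilate)
  out <- x - bl
  if (keep_baseline) attr(out, "baseline") <- bl
  out
}

#' @export
subtract_baseline.numeric <- function(x, lambda = 5000, p = 0.01, maxit = 50,
                                      tol = 1e-6, dilate = 6L, force = FALSE,
                                      keep_baseline = FALSE) {
  out <- subtract_baseline(matrix(x, 1), lambda, p, maxit, tol, dilate,
                           keep_baseline = keep_baseline)
  res <- drop(out)
  if (keep_baseline) attr(res, "baseline") <- drop(attr(out, "baseline"))
  res
}

# rows = spectra, columns = channels
als_baseline <- function(mat, lambda = 5000, p = 0.01, maxit = 50, tol = 1e-6,
                         dilate = 6L) {
  if (!all(is.finite(mat))) data_error("non-finite spectra in baseline fit")
  fit <- .als_baseline_cpp(t(mat), lambda, p, as.integer(maxit), tol,
                           as.integer(dilate))
  if (!all(fit$converged)) {
    warn(sprintf("baseline fit did not converge for %d of %d spectra; using best fit",
                 sum(!fit$converged), length(fit$converged)))
  }
  t(fit$baseline)
}

#' Bin pixels along the scan axis
#'
#' Averages non-overlapping `factor` x 1 line bins along the scan (row)
#' axis, emulating the instrument's line binning.  The mean convention
#' keeps intensities comparable across binning factors; the pixel pitch
#' scales by `factor`.
#'
#' @param cube A `sers_cube`.
#' @param factor Integer binning factor (>= 1).  Rows that do not fill a
#'   complete bin are cropped with a warning.
#' @return The binned cube.
#' @export
bin_pixels <- function(cube, factor) {
  stopifnot(inherits(cube, "sers_cube"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) config_error("bin factor must be >= 1")
  if (factor == 1) return(cube)
  d <- dim(cube$intensities)
  h2 <- d[1] %/% factor
  if (h2 < 1) config_error("bin factor %d exceeds image height %d", factor, d[1])
  if (d[1] %% factor != 0) {
    warn(sprintf("image height %d not divisible by %d; cropping %d trailing rows",
                 d[1], factor, d[1] %% factor))
  }
  idx <- rep(seq_len(h2), each = factor)
  out <- cube
  arr <- cube$intensities[seq_along(idx), , , drop = FALSE]
  # mean over each factor-row group, vectorised over columns and channels
  dim(arr) <- c(factor, h2, d[2], d[3])
  out$intensities <- array(colMeans(arr), dim = c(h2, d[2], d[3]))
  out$pixel_pitch <- cube$pixel_pitch * factor
  out$metadata$bin_factor <- cube$metadata$bin_factor * factor
  out
}

#' Band-intensity image
#'
#' Accumulates (sums) the SERS signal at a central wavenumber over the
#' closed window `center +/- halfwidth`, per pixel -- the operation behind
#' band imaging at e.g. 480 +/- 5 cm^-1 and behind the +/- 10 cm^-1
#' classifier features.
#'
#' @param cube A `sers_cube`.
#' @param center Band centre, cm^-1.
#' @param halfwidth Window half-width, cm^-1 (by convention 5 for imaging
#'   and 10 for statistics and features).  `halfwidth = 0` returns the
#'   nearest-channel slice.
#' @return A `sers_band_image` (values matrix plus band metadata).
#' @export
band_image <- function(cube, center, halfwidth = 5) {
  stopifnot(inherits(cube, "sers_cube"))
  if (halfwidth < 0) config_error("halfwidth must be >= 0")
  d <- dim(cube$intensities)
  if (halfwidth == 0) {
    ch <- wn_nearest(cube$axis, center)
    vals <- cube$intensities[, , ch]
  } else {
    ch <- wn_window(cube$axis, center, halfwidth)
    if (!length(ch)) {
      data_error("no channels in band window %g +/- %g cm^-1", center, halfwidth)
    }
    sub <- cube$intensities[, , ch, drop = FALSE]
    vals <- rowSums(sub, dims = 2)
  }
  structure(
    list(values = matrix(vals, d[1], d[2]), center = center,
         halfwidth = halfwidth, pixel_pitch = cube$pixel_pitch),
    class = "sers_band_image"
  )
}

#' @export
print.sers_band_image <- function(x, ...) {
  cat(sprintf("<sers_band_image> %g +/- %g cm^-1, %d x %d pixels, mean %.3g a.u.\n",
              x$center, x$halfwidth, nrow(x$values), ncol(x$values),
              mean(x$values)))
  invisible(x)
}

#' @export
as_tibble.sers_band_image <- function(x, ...) {
  h <- nrow(x$values); w <- ncol(x$values)
  vals <- as.vector(x$values)
  ctr <- x$center; hw <- x$halfwidth
  tibble(
    x = rep(0:(w - 1L), each = h),
    y = rep(0:(h - 1L), times = w),
    intensity = vals,
    center = ctr, halfwidth = hw
  )
}
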