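#' Baseline model parameters for the synthetic generator
#'
#' Each pixel's baseline is a degree-3 polynomial over the scaled axis plus
#' one broad Gaussian hump, with coefficients drawn per pixel around
#' per-patient means -- a smooth, patient- and pixel-varying background for
#' the baseline-subtraction stage to remove.
#'
#' @param coef_means Polynomial coefficients (intercept, linear, quadratic,
#'   cubic) on the axis scaled to `[-1, 1]`, in intensity units.
#' @param hump_amplitude,hump_center,hump_width Gaussian hump apex (a.u.),
#'   centre and SD width (cm^-1).
#' @param patient_rel_sd Relative SD of per-patient coefficient means.
#' @param pixel_rel_sd Relative SD of per-pixel coefficients around the
#'   patient means.
#' @return Named list of baseline parameters.
#' @export
baseline_params <- function(coef_means = c(100, -30, 15, -5),
                            hump_amplitude = 40, hump_center = 1100,
                            hump_width = 300, patient_rel_sd = 0.2,
                            pixel_rel_sd = 0.05) {
  if (length(coef_means) != 4) config_error("need 4 polynomial coefficients")
  if (hump_width <= 0) config_error("hump width must be positive")
  list(coef_means = coef_means, hump_amplitude = hump_amplitude,
       hump_center = hump_center, hump_width = hump_width,
       patient_rel_sd = patient_rel_sd, pixel_rel_sd = pixel_rel_sd)
}

# basis: [1, x, x^2, x^3, hump] evaluated on the axis
baseline_basis <- function(axis, params) {
  x <- 2 * (axis - min(axis)) / diff(range(axis)) - 1
  cbind(1, x, x^2, x^3,
        exp(-(axis - params$hump_center)^2 / (2 * params$hump_width^2)))
}

# draw per-pixel baseline coefficient matrix (5 x npix) around patient means
draw_baseline_coefs <- function(params, npix) {
  mu <- c(params$coef_means, params$hump_amplitude)
  pat <- mu * (1 + params$patient_rel_sd * rnorm(5))
  pat + abs(mu) * params$pixel_rel_sd *
    matrix(rnorm(5 * npix), 5, npix)
}

#' Render a synthetic SERS cube from a tissue phantom
#'
#' Each pixel's spectrum is a smooth baseline plus the sum of Lorentzian
#' marker bands whose mean amplitudes are selected by the pixel's
#' (diagnosis, region) context, scaled by a per-pixel multiplicative
#' hotspot factor (log-normal, emulating electromagnetic hotspot
#' heterogeneity of the SERS substrate), plus a per-patient per-channel
#' offset and additive Gaussian noise.  Patient-level amplitude variation
#' is a mean-one log-normal factor per band with the library's
#' `amplitude_cv`.
#'
#' A nonzero `calibration_shift` mislabels the reported axis by that many
#' cm^-1 (the stored spectra are unchanged); [calibrate()] recovers it from
#' a silicon reference.
#'
#' @param phantom A `sers_phantom`.
#' @param axis Wavenumber axis the cube is sampled on.
#' @param peak_library Long peak-library tibble (see [peak_spec()]).
#' @param baseline Baseline parameters from [baseline_params()].
#' @param noise_sd Additive per-channel Gaussian noise SD (a.u.).
#' @param hotspot_cv CV of the per-pixel multiplicative hotspot factor.
#' @param patient_sd SD of the per-patient per-channel additive offset.
#' @param calibration_shift Axis mislabelling in cm^-1.
#' @param seed Integer seed (deterministic rendering).
#' @param keep_truth If `TRUE`, attach the noiseless ground truth
#'   (baseline matrix and peak signal) for oracle tests.
#' @return A `sers_cube`.
#' @export
render_cube <- function(phantom, axis = wn_axis(240, 1800, 2),
                        peak_library = default_peak_library(),
                        baseline = baseline_params(), noise_sd = 8,
                        hotspot_cv = 0.25, patient_sd = 6,
                        calibration_shift = 0, seed = 1, keep_truth = FALSE) {
  if (noise_sd < 0) config_error("noise_sd must be >= 0")
  if (hotspot_cv < 0) config_error("hotspot_cv must be >= 0")
  check_axis(axis)
  check_peak_library(peak_library, axis)

  labs <- mask_labels(phantom$mask)
  h <- nrow(labs); w <- ncol(labs); npix <- h * w
  nch <- length(axis)

  lib <- peak_library[peak_library$diagnosis == phantom$diagnosis, ]
  peaks <- unique(lib[, c("center", "width", "amplitude_cv")])

  # patient-level amplitude factors: mean-one log-normal per band
  amp_factor <- with_seed(child_seed(seed, 1), {
    sdlog <- sqrt(log(1 + peaks$amplitude_cv^2))
    rlnorm(nrow(peaks), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })

  # region context spectra: regions x channels
  regions <- c("nest", "stroma", "adipose", "normal")
  L <- outer(seq_len(nrow(peaks)), seq_len(nch), function(i, j) {
    lorentz(axis[j], peaks$center[i], peaks$width[i])
  })
  region_spec <- vapply(regions, function(r) {
    amp <- lib$amplitude[match(
      paste(peaks$center, r), paste(lib$center, lib$region))]
    colSums((amp * amp_factor) * L)
  }, numeric(nch))  # nch x 4

  pix_region <- label_region(as.vector(labs))
  signal <- matrix(0, npix, nch)
  known <- !is.na(pix_region)
  if (any(known)) {
    signal[known, ] <- t(region_spec)[match(pix_region[known], regions), ,
                                      drop = FALSE]
  }

  hotspot <- with_seed(child_seed(seed, 2), {
    if (hotspot_cv > 0) {
      sdlog <- sqrt(log(1 + hotspot_cv^2))
      rlnorm(npix, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, npix)
  })

  coefs <- with_seed(child_seed(seed, 3), draw_baseline_coefs(baseline, npix))
  base_mat <- t(baseline_basis(axis, baseline) %*% coefs)  # npix x nch

  offset <- with_seed(child_seed(seed, 4), rnorm(nch, 0, patient_sd))

  noise <- with_seed(child_seed(seed, 5), {
    if (noise_sd > 0) matrix(rnorm(npix * nch, 0, noise_sd), npix, nch)
    else matrix(0, npix, nch)
  })

  y <- base_mat + hotspot * signal +
    matrix(offset, npix, nch, byrow = TRUE) + noise

  cube <- sers_cube(
    matrix_to_cube_array(y, h, w), axis + calibration_shift,
    metadata = list(patient_id = phantom$patient_id,
                    diagnosis = phantom$diagnosis)
  )
  if (keep_truth) {
    attr(cube, "truth") <- list(
      baseline = base_mat, signal = hotspot * signal, offset = offset,
      amp_factor = setNames(amp_factor, peaks$center),
      calibration_shift = calibration_shift
    )
  }
  cube
}

#' Silicon calibration reference spectrum
#'
#' A single narrow Lorentzian line whose apex sits at the silicon phonon
#' mode (520 cm^-1) displaced by `shift` -- the reference measured before
#' tissue acquisition to calibrate the wavenumber axis.
#'
#' @param axis Wavenumber axis.
#' @param shift Miscalibration in cm^-1; the apex renders at `520 + shift`.
#' @param width HWHM of the line, cm^-1.
#' @param amplitude Apex intensity, a.u.
#' @return Tibble with `wavenumber` and `intensity`.
#' @examples
#' si <- silicon_reference(wn_axis(), shift = 4)
#' si$wavenumber[which.max(si$intensity)]
#' @export
silicon_reference <- function(axis, shift = 0, width = 3, amplitude = 1000) {
  check_axis(axis)
  apex <- 520 + shift
  if (apex < min(axis) || apex > max(axis)) {
    data_error("silicon apex %.1f cm^-1 lies outside the axis [%g, %g]",
               apex, min(axis), max(axis))
  }
  tibble(wavenumber = axis, intensity = amplitude * lorentz(axis, apex, width))
}
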