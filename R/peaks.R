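#' The 27 stromal marker wavenumbers
#'
#' The wavenumbers (cm^-1) of the differentially expressed SERS bands used
#' as classifier features, ordered by decreasing discriminative importance.
#' They include the assigned redox-metabolite bands -- 480 cm^-1
#' (polysulfide, elevated in invasive cancer stroma) and 974 cm^-1
#' (hypotaurine, depleted there) -- alongside 382, 1140 and 1250 cm^-1 and
#' 22 further fingerprint-region bands.
#'
#' @return Numeric vector of 27 wavenumbers in cm^-1.
#' @export
default_marker_wavenumbers <- function() {
  c(382, 974, 480, 256, 888, 1250, 334, 1504, 1028, 840, 916, 1536, 1412,
    696, 760, 1140, 616, 1378, 642, 592, 1308, 532, 666, 798, 1570, 576,
    1082)
}

# control band: purine phospho-nucleotides (ATP/ADP), equal in both classes
control_wavenumber <- function() 722

# Dominance design of the default library. D = DCIS-dominant (DCIS > IBC in
# stroma), I = IBC-dominant. 382/974/1140/1250 are D and 480 I by
# construction; the free bands are split 19 D / 8 I with signs alternated
# among close neighbours so that overlapping Lorentzian tails of adjacent
# bands cancel instead of merging.
default_i_dominant <- function() c(256, 480, 592, 642, 696, 888, 1028, 1536)

#' Build a peak specification table
#'
#' A peak library is a long tibble with one row per (band, diagnosis,
#' region) context.  `amplitude` is the mean Lorentzian apex amplitude
#' (arbitrary units) for pixels of that region in a patient of that
#' diagnosis; `amplitude_cv` is the coefficient of variation of the
#' patient-level amplitude factor; `width` is the half-width at
#' half-maximum in cm^-1.
#'
#' @param center Band centre, cm^-1.
#' @param width HWHM, cm^-1.
#' @param amplitudes Named list mapping `diagnosis.region` (for example
#'   `IBC.stroma`) to a mean amplitude; unnamed contexts default to 0.
#' @param amplitude_cv Patient-level coefficient of variation.
#' @return Tibble with columns center, width, amplitude_cv, diagnosis,
#'   region, amplitude.
#' @export
peak_spec <- function(center, width = 4, amplitudes = list(), amplitude_cv = 0.15) {
  if (width <= 0) config_error("peak width must be positive (center %g)", center)
  grid <- tidyr::expand_grid(
    diagnosis = c("DCIS", "IBC"),
    region = c("nest", "stroma", "adipose", "normal")
  )
  amp <- vapply(paste(grid$diagnosis, grid$region, sep = "."), function(k) {
    v <- amplitudes[[k]]
    if (is.null(v)) 0 else as.numeric(v)
  }, numeric(1))
  if (any(amp < 0)) config_error("peak amplitudes must be >= 0 (center %g)", center)
  tibble(
    center = center, width = width, amplitude_cv = amplitude_cv,
    diagnosis = grid$diagnosis, region = grid$region, amplitude = unname(amp)
  )
}

# uniform amplitude over a set of contexts
amp_ctx <- function(value, diagnoses = c("DCIS", "IBC"),
                    regions = c("nest", "stroma", "adipose", "normal")) {
  keys <- as.vector(outer(diagnoses, regions, paste, sep = "."))
  setNames(as.list(rep(value, length(keys))), keys)
}

#' Default synthetic peak library
#'
#' The shipped library carries the 27 marker bands with class-dependent
#' stromal amplitudes (DCIS-dominant bands: mean apex `amp_high` in DCIS
#' stroma and `amp_low` in IBC stroma; IBC-dominant bands reversed -- so
#' IBC stroma has the elevated 480 cm^-1 polysulfide band and the depressed
#' 974 cm^-1 hypotaurine band), equal non-differential amplitudes in cancer
#' nests, adipose and normal gland, and the 722 cm^-1 purine-nucleotide
#' control band equal in both diagnoses everywhere.
#'
#' With the default `amplitude_cv` the stromal between-class difference is
#' about 3 patient-level pooled standard deviations at every marker band.
#'
#' @param amp_high,amp_low Mean apex amplitudes (a.u.) of the dominant and
#'   non-dominant class in stroma.
#' @param width HWHM of every band, cm^-1.
#' @param amplitude_cv Patient-level amplitude coefficient of variation.
#' @return A long peak-library tibble (see [peak_spec()]).
#' @export
default_peak_library <- function(amp_high = 100, amp_low = 55, width = 4,
                                 amplitude_cv = 0.15) {
  markers <- default_marker_wavenumbers()
  i_dom <- default_i_dominant()
  specs <- lapply(markers, function(w) {
    hi_dcis <- !(w %in% i_dom)
    amps <- c(
      list(DCIS.stroma = if (hi_dcis) amp_high else amp_low,
           IBC.stroma  = if (hi_dcis) amp_low else amp_high),
      amp_ctx(70, regions = "nest"),
      amp_ctx(60, regions = "adipose"),
      amp_ctx(40, regions = "normal")
    )
    peak_spec(w, width = width, amplitudes = amps, amplitude_cv = amplitude_cv)
  })
  control <- peak_spec(control_wavenumber(), width = width,
                       amplitudes = amp_ctx(80), amplitude_cv = amplitude_cv)
  dplyr::bind_rows(c(specs, list(control)))
}

# validate a peak library against an axis; every band with any positive
# amplitude must have its centre on the axis
check_peak_library <- function(lib, axis) {
  need <- c("center", "width", "amplitude_cv", "diagnosis", "region", "amplitude")
  if (!all(need %in% names(lib))) {
    config_error("peak library must have columns %s", paste(need, collapse = ", "))
  }
  if (any(lib$width <= 0)) config_error("peak widths must be positive")
  if (any(lib$amplitude < 0)) config_error("peak amplitudes must be >= 0")
  live <- unique(lib$center[lib$amplitude > 0])
  out <- live[live < min(axis) | live > max(axis)]
  if (length(out)) {
    data_error("peak at %g cm^-1 lies outside the wavenumber axis [%g, %g]",
               out[1], min(axis), max(axis))
  }
  invisible(lib)
}

# Lorentzian profile with unit apex
lorentz <- function(wn, center, hwhm) 1 / (1 + ((wn - center) / hwhm)^2)

# mean apex amplitude matrix: bands x regions for one diagnosis
amplitude_matrix <- function(lib, diagnosis) {
  sub <- lib[lib$diagnosis == diagnosis, ]
  tidyr::pivot_wider(sub[, c("center", "width", "amplitude_cv", "region", "amplitude")],
                     names_from = "region", values_from = "amplitude")
}
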