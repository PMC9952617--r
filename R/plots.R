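#' Plot a band-intensity image
#'
#' @param object A `sers_band_image`.
#' @param ... Unused.
#' @return A ggplot raster of the band image (y flipped to image
#'   orientation).
#' @export
autoplot.sers_band_image <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "a.u.") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("SERS band image %g ± %g cm⁻¹",
                      object$center, object$halfwidth),
      x = "x (px)", y = "y (px)")
}

#' Plot an annotation mask
#'
#' @param object A `sers_mask`.
#' @param ... Unused.
#' @return A ggplot raster of the annotation labels.
#' @export
autoplot.sers_mask <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "annotation")
}

#' Plot the differential-peak profile
#'
#' The per-channel Welch t statistic (DCIS minus IBC orientation) across
#' the fingerprint region, with detected peaks marked and coloured by
#' dominance.
#'
#' @param object A `sers_diff_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sers_diff_report <- function(object, ...) {
  ch <- object$channels
  pk <- object$peaks
  p <- ggplot2::ggplot(ch, ggplot2::aes(.data$wavenumber, .data$t)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "wavenumber (cm⁻¹)",
                  y = "Welch t (DCIS − IBC)",
                  colour = "dominance")
  if (nrow(pk)) {
    p <- p + ggplot2::geom_point(
      data = pk, ggplot2::aes(colour = .data$dominance), size = 2) +
      ggplot2::scale_colour_manual(values = c(D = "#2166ac", I = "#b2182b"))
  }
  p
}

#' Plot per-patient IBC mesh ratios
#'
#' @param object A patient-prediction tibble from [patient_aggregate()].
#' @param ... Unused.
#' @return A ggplot bar chart of the IBC ratio per patient with the 0.5
#'   decision line.
#' @export
plot_patient_ratios <- function(object, ...) {
  df <- dplyr::arrange(as_tibble(object), .data$ratio_ibc)
  df$patient_id <- factor(df$patient_id, levels = df$patient_id)
  ggplot2::ggplot(df, ggplot2::aes(.data$patient_id, .data$ratio_ibc,
                                   fill = .data$predicted_category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ratio of meshes predicted IBC",
                  fill = "category")
}
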