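#' Plot a transverse profile in the overlay style
#'
#' Two maximum-normalized curves (actin, protein) against transverse
#' distance, origin at the outer stereocilia row.
#'
#' @param object a [transverse_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.transverse_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("actin", "protein"),
                            names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(df, ggplot2::aes(.data$distance_nm, .data$intensity,
                                   colour = .data$channel)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = c(actin = "#9633ad",
                                            protein = "#1b9e50")) +
    ggplot2::labs(x = "distance from outer row (nm)",
                  y = "normalized intensity", colour = NULL) +
    ggplot2::theme_classic()
}

#' Plot the averaged stereocilium
#'
#' Shows both channels of the aligned, averaged, background-subtracted
#' stereocilium; the outward normal points up, interior rows lie below the
#' centre.
#'
#' @param object an `average_stereocilium` (from [subtract_background()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.average_stereocilium <- function(object, ...) {
  k <- object$roi_size_px
  d <- ((1:k) - (k + 1) / 2) * object$pixel_size_nm
  g <- expand.grid(y = d, x = d)
  norm <- function(m) { m[is.na(m)] <- 0; m / max(m, 1e-12) }
  df <- dplyr::bind_rows(
    tibble::tibble(g, value = c(norm(object$actin)), channel = "actin"),
    tibble::tibble(g, value = c(norm(object$protein)), channel = "protein"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "intra-row axis (nm)", y = "inter-row axis (nm)",
                  fill = "norm.") +
    ggplot2::theme_minimal()
}

#' Plot axial (horizontal / vertical) profiles of the averaged stereocilium
#'
#' @param axial the tibble from [axial_profiles()].
#' @return a ggplot with one panel per axis.
#' @export
plot_axial_profiles <- function(axial) {
  df <- tidyr::pivot_longer(axial, c("actin", "protein"),
                            names_to = "channel", values_to = "intensity")
  df <- dplyr::mutate(
    df,
    intensity = .data$intensity / max(.data$intensity),
    .by = c("axis", "channel"))
  ggplot2::ggplot(df, ggplot2::aes(.data$distance_nm, .data$intensity,
                                   colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~axis) +
    ggplot2::scale_colour_manual(values = c(actin = "#9633ad",
                                            protein = "#1b9e50")) +
    ggplot2::labs(x = "distance (nm)", y = "normalized intensity",
                  colour = NULL) +
    ggplot2::theme_classic()
}
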