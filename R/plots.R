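#' Plot D-band banding
#'
#' Crosslink z positions with the recovered band centers and the
#' overlap/gap classification of adjacent intervals.
#'
#' @param object A `dband_result` from [dband_periodicity()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dband_result
#' @export
autoplot.dband_result <- function(object, ...) {
  pts <- tibble::tibble(z = object$z)
  bands <- tidy(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$z, y = 0)) +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$center_lo, xmax = .data$center_hi,
                   ymin = -0.5, ymax = 0.5, fill = .data$class),
      inherit.aes = FALSE, alpha = 0.3) +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 0.8) +
    ggplot2::geom_vline(xintercept = object$centers, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(overlap = "#1b9e77", gap = "#d95f02")) +
    ggplot2::labs(x = "axial position (nm)", y = NULL, fill = NULL,
                  title = sprintf("D-period %.2f nm (overlap %.1f + gap %.1f)",
                                  object$d_period_nm, object$overlap_nm,
                                  object$gap_nm)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot the transverse cross-section of a fibril system
#'
#' Molecule representative points projected onto the plane perpendicular to
#' the fibril axis.
#'
#' @param object A [fibril_system()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fibril_system
#' @export
autoplot.fibril_system <- function(object, ...) {
  pts <- molecule_points(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x / 10, y = .data$y / 10)) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = sprintf("%d molecules", nrow(pts))) +
    ggplot2::theme_minimal()
}

#' Plot a radial density profile
#'
#' @param object A `density_profile` from [density_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$r_mid, y = .data$density)) +
    ggplot2::geom_col(width = object$profile$r_outer[1] -
                        object$profile$r_inner[1]) +
    ggplot2::labs(x = "radial distance (nm)", y = "points / nm²",
                  title = sprintf("occupancy sd %.3f", object$occupancy_sd)) +
    ggplot2::theme_minimal()
}
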