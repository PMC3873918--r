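# ggplot2 views of the pipeline's result types.

#' Plot cellular tracks
#'
#' Tracks in image orientation (y axis reversed so the plot matches the
#' frames).
#'
#' @param tracks Track tibble (`cell_id`, `frame`, `x`, `y`).
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks) {
  tracks <- validate_tracks(tracks)
  ggplot2::ggplot(tracks,
                  ggplot2::aes(.data$x, .data$y, group = .data$cell_id)) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("%d tracks", length(unique(tracks$cell_id)))) +
    ggplot2::theme_minimal()
}

#' Rose plot of migration directions
#'
#' Circular histogram of trajectory angles, compass convention (0 deg = east,
#' 90 deg = up).
#'
#' @param kinematics A kinematics tibble from [compute_kinematics()].
#' @param bin_width_deg Bin width in degrees.
#' @return A ggplot object.
#' @export
plot_direction_rose <- function(kinematics, bin_width_deg = 15) {
  d <- tibble::as_tibble(kinematics) |>
    dplyr::filter(!is.na(.data$theta_trajectory_deg))
  ggplot2::ggplot(d, ggplot2::aes(.data$theta_trajectory_deg)) +
    ggplot2::geom_histogram(binwidth = bin_width_deg,
                            boundary = 0, closed = "left") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = "angle of trajectory (deg)", y = "cells") +
    ggplot2::theme_minimal()
}

#' Population deflection statistics over time
#'
#' Mean absolute angle of deflection per frame — the population's migration
#' persistence readout (lower = more persistent).
#'
#' @param summary A tibble from [summarize_population()].
#' @return A ggplot object.
#' @export
plot_deflection_trend <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$frame, .data$avg_abs_deflection_deg)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "frame",
                  y = "mean |angle of deflection| (deg)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PRW persistence fit
#'
#' MSD data points with the fitted persistent-random-walk curve.
#'
#' @param object A `prw_fit` from [fit_persistence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prw_fit
#' @export
autoplot.prw_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(t_min = seq(min(d$t_min), max(d$t_min),
                                     length.out = 200))
  if (!is.na(object$P)) {
    grid$msd_um2 <- prw_msd(grid$t_min, object$S, object$P, object$n_d)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$t_min, .data$msd_um2)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lag time (min)", y = expression(MSD ~ (mu * m^2)),
                  title = sprintf("S = %.3g um/min, P = %.3g min%s",
                                  object$S, object$P,
                                  if (object$converged) "" else " (flagged)")) +
    ggplot2::theme_minimal()
  if (!is.na(object$P)) {
    p <- p + ggplot2::geom_line(data = grid, color = "red")
  }
  p
}

#' Plot a leading-edge PRMI profile
#'
#' @param profile Tibble from [leading_edge_profile()].
#' @return A ggplot object.
#' @export
plot_prmi_profile <- function(profile) {
  d <- dplyr::mutate(profile,
                     window = sprintf("frames %d-%d", .data$window_start,
                                      .data$window_end))
  ggplot2::ggplot(d, ggplot2::aes(.data$bin_start_um, .data$prmi_deg,
                                  color = .data$window, group = .data$window)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance from leading edge (um)",
                  y = "PRMI (deg)", color = NULL) +
    ggplot2::theme_minimal()
}
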