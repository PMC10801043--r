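# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_line
#'   geom_col coord_polar coord_equal facet_wrap labs scale_fill_viridis_c
#'   position_dodge geom_errorbar theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a tilt-density grid
#'
#' Square-cell density of raw pad samples: pitch (forward/backward) on
#' the vertical axis, yaw (left-right rotation) on the horizontal,
#' lighter cells holding more samples.
#'
#' @param object a `nav_density_grid` from [density_grid()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.nav_density_grid <- function(object, ...) {
  bw <- attr(object, "bin_width") %||% 0.1
  ggplot(object, aes(x = .data$yaw_bin, y = .data$pitch_bin,
                     fill = .data$count)) +
    geom_tile(width = bw, height = bw) +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "yaw (left-right tilt)", y = "pitch (toe-heel tilt)",
         fill = "samples") +
    theme_minimal()
}

#' Polar view of recall errors
#'
#' Each trial as a point at (theta, r): angle of the response around the
#' item's encoding location, distance as radius. Points near the centre
#' are accurate recalls; trials with undefined angle (r = 0) are omitted.
#'
#' @param trials a per-trial table carrying `r` and `theta_deg` (run
#'   [polar_error()] first if needed) plus `condition` and `landmark`.
#' @return a ggplot object.
#' @export
plot_polar_errors <- function(trials) {
  if (!all(c("r", "theta_deg") %in% names(trials))) {
    trials <- polar_error(trials)
  }
  assert_cols(trials, c("condition", "landmark"), "trials")
  ggplot(filter(trials, !is.na(.data$theta_deg)),
         aes(x = .data$theta_deg, y = .data$r, colour = .data$condition)) +
    geom_point(alpha = 0.7) +
    coord_polar(theta = "x") +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = c(0, 90, 180, 270)) +
    facet_wrap(~landmark) +
    labs(x = "angular deviation (degrees)", y = "distance error (vu)",
         colour = "condition") +
    theme_minimal()
}

#' Condition means of a scored questionnaire
#'
#' Bar chart of per-condition questionnaire means with +/- 1 SD bars.
#'
#' @param summary a summary tibble with columns `condition`, `mean`,
#'   `sd` (e.g. `sus_table` or `itc_ne_table` of a study report).
#' @param label y-axis label.
#' @return a ggplot object.
#' @export
plot_questionnaire_summary <- function(summary, label = "score") {
  assert_cols(summary, c("condition", "mean", "sd"), "summary")
  ggplot(summary, aes(x = .data$condition, y = .data$mean)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.2) +
    labs(x = NULL, y = label) +
    theme_minimal()
}
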