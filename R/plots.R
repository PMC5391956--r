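# ggplot2 views of the pipeline's result types.

#' Plot forward ankle trajectories with detected foot events
#'
#' The classic gait-event picture: both ankles' forward positions over time,
#' crossings marked.
#'
#' @param gp a `gait_parameters` object from [analyze_gait()] (carries the
#'   events and axes), or `NULL` to plot trajectories only.
#' @param ankles wide ankle tibble (required when `gp` lacks one; otherwise
#'   taken from the call).
#' @param series alternatively, a `fused_series` to extract ankles from.
#' @return a ggplot object.
#' @export
plot_ankle_forward <- function(gp = NULL, ankles = NULL, series = NULL) {
  if (is.null(ankles)) {
    stopifnot(!is.null(series))
    ankles <- ankle_trajectories(series)
  }
  axes <- if (!is.null(gp)) gp$axes else estimate_axes(ankles)
  a <- project_ankles(dplyr::filter(ankles, .data$valid), axes)
  long <- tidyr::pivot_longer(a[, c("time", "lf", "rf")], -"time",
                              names_to = "foot", values_to = "forward")
  long$foot <- ifelse(long$foot == "lf", "left", "right")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$forward,
                                          colour = .data$foot)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(left = "firebrick",
                                            right = "steelblue")) +
    ggplot2::labs(x = "time (s)", y = "forward ankle position (m)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(gp) && nrow(gp$events)) {
    ev <- gp$events
    ev$forward <- stats::approx(a$time, (a$lf + a$rf) / 2, ev$time, rule = 2)$y
    p <- p + ggplot2::geom_point(data = ev,
                                 ggplot2::aes(x = .data$time, y = .data$forward),
                                 inherit.aes = FALSE, shape = 4, size = 3)
  }
  p
}

#' Bland-Altman plot
#'
#' Pairwise mean against difference with the bias line and the
#' bias +/- RPC limits.
#'
#' @param a,b paired numeric vectors.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(a, b, title = NULL) {
  pd <- bland_altman_plot_data(a, b)
  ggplot2::ggplot(pd$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(data = pd$lines,
                        ggplot2::aes(yintercept = .data$value,
                                     linetype = .data$name)) +
    ggplot2::scale_linetype_manual(values = c(bias = "solid", upper = "dashed",
                                              lower = "dashed"), guide = "none") +
    ggplot2::labs(x = "mean of the two systems", y = "difference (A - B)",
                  title = title) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a fused series: joint trajectories over time
#'
#' @param object a `fused_series`.
#' @param joints joints to show (default the two ankles).
#' @param coord which coordinate, `"x"`, `"y"` or `"z"` (default `"x"`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fused_series <- function(object, joints = c("AnkleLeft", "AnkleRight"),
                                  coord = "x", ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$joint %in% joints,
                     .data$valid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data[[coord]],
                                  colour = .data$joint)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = paste0(coord, " (m)"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot gait parameters: per-step values by foot
#'
#' @param object a `gait_parameters` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gait_parameters <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  colour = .data$foot)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "foot") +
    ggplot2::theme_minimal()
}
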