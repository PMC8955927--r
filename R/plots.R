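#' Plot a fitted mixture over the binned error distribution
#'
#' Histogram of the fitted trials in 4-degree bins (the conventional display
#' bin width for report-error distributions) with the fitted mixture density
#' overlaid.
#'
#' @param object A `mixture_fit`.
#' @param binwidth Histogram bin width in degrees.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixture_fit <- function(object, binwidth = 4, ...) {
  grid <- seq(-180, 180, by = 0.5)
  curve <- tibble::tibble(
    error_deg = grid,
    density = dmixture(pmin(pmax(grid, -179.999), 180), object$spec,
                       object$options$clip_mode)
  )
  ggplot2::ggplot(tibble::tibble(error_deg = object$errors),
                  ggplot2::aes(x = .data$error_deg)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, boundary = -180,
                            fill = "grey80", colour = "grey50",
                            linewidth = 0.2) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$density),
                       colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(x = "report error (deg)", y = "density",
                  title = sprintf("%d-Gaussian + uniform fit (BIC %.1f)",
                                  n_components(object$spec), object$bic)) +
    ggplot2::theme_minimal()
}

#' Heatmap of BIC winners over design cells
#'
#' @param object A [winner_map()].
#' @param ... Unused.
#' @return A ggplot object: subjects against condition cells, tile colour
#'   the winning number of components, tile label the runner-up.
#' @export
autoplot.winner_map <- function(object, ...) {
  d <- tibble::as_tibble(object)
  xvar <- if ("cue_delay_ms" %in% names(d) &&
              dplyr::n_distinct(d$cue_delay_ms) > 1) "cue_delay_ms" else "set_size"
  d$cell <- interaction(d[[xvar]],
                        d$report_condition %||% "", sep = " / ")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = .data$subject_id,
                                  fill = factor(.data$winner))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$runner_up), size = 3,
                       colour = "grey20") +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "winner n") +
    ggplot2::labs(x = sprintf("%s / condition", xvar), y = "subject",
                  title = "Best-fitting number of Gaussian components (label: runner-up)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Component SDs against cue delay
#'
#' @param object A `trend_test` (or a tibble binding several).
#' @param ... Unused.
#' @return A ggplot object: per-subject SD trajectories with the mean
#'   overlaid, faceted by component when several are present.
#' @export
autoplot.trend_test <- function(object, ...) {
  wide <- attr(object, "sigma_matrix")
  long <- tidyr::pivot_longer(wide, -"subject_id",
                              names_to = "cue_delay_ms", values_to = "sd") |>
    dplyr::mutate(cue_delay_ms = as.numeric(.data$cue_delay_ms))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cue_delay_ms, y = .data$sd)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       colour = "grey70") +
    ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1,
                          colour = "#b2182b") +
    ggplot2::labs(x = "cue delay (ms)", y = "component SD (deg)",
                  title = sprintf("%s vs cue delay: F(%d,%d) = %.2f, p = %.3f",
                                  object$component[1], object$df1[1],
                                  object$df2[1], object$f_statistic[1],
                                  object$p_value[1])) +
    ggplot2::theme_minimal()
}

#' Intake and precision curves
#'
#' @param summaries Output of [condition_summaries()].
#' @param x Name of the condition axis (`"set_size"` or `"cue_delay_ms"`).
#' @return A ggplot object with intake and precision panels.
#' @export
plot_condition_summaries <- function(summaries, x = "cue_delay_ms") {
  long <- summaries |>
    tidyr::pivot_longer(c("intake", "precision"), names_to = "measure",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[x]], y = .data$value,
                                     colour = .data$report_condition)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = x, y = NULL, colour = "condition") +
    ggplot2::theme_minimal()
}
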