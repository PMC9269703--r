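# ggplot2 displays for the main result types.

#' Plot a mean cycle with its SD band
#'
#' Shows the pointwise mean of all normalized cycles of one channel as a
#' line, with a ribbon of +/- 1 SD across cycles, optionally split by
#' group — the standard summary view of segmented bending-and-return
#' cycles.
#'
#' @param cycles A `br_cycleset`, or a row-bound tibble of several with a
#'   `group` column.
#' @param channel Internal channel name (default `"SENS2_Gyr_Y"`, the
#'   flexion-axis pelvis angular velocity).
#' @return A ggplot object.
#' @export
plot_mean_cycle <- function(cycles, channel = "SENS2_Gyr_Y") {
  df <- tibble::as_tibble(cycles)
  if (!"group" %in% names(df)) {
    df$group <- attr(cycles, "group") %||% "all"
  }
  summ <- df |>
    dplyr::group_by(.data$group, .data$itime) |>
    dplyr::summarise(
      mean = mean(.data[[channel]]),
      sd = if (dplyr::n() > 1) stats::sd(.data[[channel]]) else 0,
      .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$itime, y = .data$mean,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "normalized time (itime)",
                  y = channel_display(channel),
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_mean_cycle
#' @param object,x A `br_cycleset`.
#' @param ... Passed on to [plot_mean_cycle()].
#' @export
autoplot.br_cycleset <- function(object, ...) plot_mean_cycle(object, ...)

#' Plot a classifier benchmark
#'
#' Dot-and-error-bar display of accuracy and AUC (mean +/- SD over
#' repetitions) per algorithm.
#'
#' @param object A `br_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.br_benchmark <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"algorithm",
                        names_to = c("metric", ".value"),
                        names_pattern = "(accuracy|auc)_(mean|sd)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean,
                                     y = stats::reorder(.data$algorithm,
                                                        .data$mean))) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$mean - .data$sd,
                                          xmax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "score (mean ± SD over repetitions)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sequential-feature-selection tally
#'
#' Horizontal bars of first- and second-place counts per feature.
#'
#' @param object A `br_sfs`.
#' @param top Show the `top` most-selected features (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.br_sfs <- function(object, top = 10, ...) {
  df <- utils::head(tibble::as_tibble(object), top) |>
    tidyr::pivot_longer(c("first", "second"), names_to = "rank",
                        values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count,
                                   y = stats::reorder(.data$feature,
                                                      .data$count),
                                   fill = .data$rank)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = sprintf("selections in %d runs",
                              attr(object, "total_runs")),
                  y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
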