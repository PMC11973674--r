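# ggplot2 views of recordings and feature series.

#' Plot a stretch of a lesion recording
#'
#' Three stacked channel traces around a chosen time relative to ablation.
#'
#' @param record A `lesion_record`.
#' @param t_rel_s Centre of the plotted stretch, seconds relative to
#'   ablation (default 0).
#' @param span_s Width of the stretch in seconds (default 4).
#' @return A ggplot.
#' @export
plot_record <- function(record, t_rel_s = 0, span_s = 4) {
  stopifnot(inherits(record, "lesion_record"))
  fs <- record$fs
  center <- record$ablation_index + round(t_rel_s * fs)
  half <- round(span_s / 2 * fs)
  idx <- max(1, center - half):min(nrow(record$signals), center + half)
  d <- record$signals[idx, ] |>
    dplyr::mutate(t_rel_s = (.data$sample - record$ablation_index) / fs) |>
    tidyr::pivot_longer(c("ecg", "bipolar", "unipolar"),
                        names_to = "channel", values_to = "mV") |>
    dplyr::mutate(channel = factor(.data$channel,
                                   c("ecg", "bipolar", "unipolar")))
  ggplot2::ggplot(d, ggplot2::aes(.data$t_rel_s, .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y") +
    ggplot2::labs(x = "time relative to ablation (s)", y = "mV",
                  title = record$meta$lesion_id,
                  subtitle = record$meta$group) +
    ggplot2::theme_minimal()
}

#' Plot group feature time courses
#'
#' Median and interquartile ribbon of a (normalized) feature series per
#' group over time — the standard view of post-ablation recovery dynamics.
#'
#' @param features Feature tibble (one or more lesions).
#' @param band Channel/band to plot (default `"unipolar_LF"`).
#' @param value Value column: `"normalized"` (default) or `"value_mV"`.
#' @param group_col Grouping column (default `"group"`).
#' @return A ggplot.
#' @export
plot_feature_series <- function(features, band = "unipolar_LF",
                                value = "normalized",
                                group_col = "group") {
  d <- features |>
    dplyr::filter(.data$channel_band == band, !is.na(.data[[value]])) |>
    dplyr::group_by(.data[[group_col]], .data$t_rel_s) |>
    dplyr::summarise(
      med = stats::median(.data[[value]]),
      q1 = stats::quantile(.data[[value]], 0.25),
      q3 = stats::quantile(.data[[value]], 0.75),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(.data$t_rel_s, .data$med,
                                  colour = .data[[group_col]],
                                  fill = .data[[group_col]])) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time relative to ablation (s)",
                  y = if (value == "normalized") "normalized peak-to-peak"
                      else "peak-to-peak (mV)",
                  title = band) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a cohort result
#'
#' Side effect-free shortcut for [plot_feature_series()] on a
#' [run_pipeline()] result.
#'
#' @param object A `cohort_result`.
#' @param band Channel/band (default `"unipolar_LF"`).
#' @param ... Passed to [plot_feature_series()].
#' @return A ggplot.
#' @export
autoplot.cohort_result <- function(object, band = "unipolar_LF", ...) {
  plot_feature_series(object$features, band = band, ...)
}
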