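# ggplot2 visualisations for traces and protocol runs.

#' Plot a multichannel trace
#'
#' Faceted time series of MAP (with the active target overlaid), CVP,
#' infusion rate, and the continuous lactate channel when present.
#'
#' @param trace a trace tibble (e.g. `protocol_result$trace`).
#' @param channels which channels to show.
#' @return a ggplot object.
#' @export
plot_trace <- function(trace,
                       channels = c("map_mmHg", "cvp_mmHg",
                                    "infusion_mL_min", "lactate_true")) {
  channels <- intersect(channels, names(trace))
  long <- trace |>
    dplyr::select(dplyr::all_of(c("time_min", channels))) |>
    tidyr::pivot_longer(-"time_min", names_to = "channel", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL)
  if ("map_mmHg" %in% channels && "target_mmHg" %in% names(trace)) {
    tgt <- tibble::tibble(time_min = trace$time_min,
                          value = trace$target_mmHg, channel = "map_mmHg")
    p <- p + ggplot2::geom_line(data = tgt, colour = "red3",
                                linetype = "dashed", na.rm = TRUE)
  }
  p
}

#' @rdname plot_trace
#' @param object a `protocol_result`.
#' @param ... passed to [plot_trace()].
#' @method autoplot protocol_result
#' @export
autoplot.protocol_result <- function(object, ...) {
  plot_trace(object$trace, ...) +
    ggplot2::ggtitle("two-event hemorrhage/resuscitation protocol")
}

#' Cohort lactate accumulation by anesthetic stratum
#'
#' @param object a `cohort_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cohort_result
#' @export
autoplot.cohort_result <- function(object, ...) {
  ggplot2::ggplot(object$subjects,
                  ggplot2::aes(x = .data$anesthetic,
                               y = .data$lactate_slope_mmol_L_hr)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::labs(x = NULL, y = "lactate accumulation (mmol/L/hr)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
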