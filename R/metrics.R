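# Controller-performance metric suite: median performance error family,
# band effectiveness (including the one-sided resuscitation effectiveness),
# transient measures, and infusion-rate statistics, plus the two-event
# ratio report.

check_trace_metrics <- function(trace) {
  need <- c("time_min", "map_mmHg", "target_mmHg")
  missing <- setdiff(need, names(trace))
  if (length(missing)) {
    stop("trace is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(trace)) stop("trace is empty", call. = FALSE)
  if (any(!is.finite(trace$target_mmHg)) || any(trace$target_mmHg <= 0)) {
    stop("trace target must be positive at all samples", call. = FALSE)
  }
  invisible(trace)
}

#' Performance-error series
#'
#' `PE_t = 100 * (map_t - target_t) / target_t`, the control error as a
#' percentage of the instantaneous active target (so safety-rule target
#' reductions change the denominator from the reduction time onward).
#'
#' @param trace tibble with `time_min`, `map_mmHg` and `target_mmHg` columns.
#' @return tibble with `time_min` and `pe_pct`.
#' @export
performance_error <- function(trace) {
  check_trace_metrics(trace)
  tibble::tibble(
    time_min = trace$time_min,
    pe_pct = 100 * (trace$map_mmHg - trace$target_mmHg) / trace$target_mmHg
  )
}

#' Median performance error, median absolute performance error, and wobble
#'
#' `mdpe = median(PE)`, `mdape = median(|PE|)`,
#' `wobble = median(|PE - mdpe|)`; even-length medians are averaged.
#'
#' @param pe numeric performance-error series in percent (e.g. the `pe_pct`
#'   column of [performance_error()]).
#' @return one-row tibble with `mdpe`, `mdape`, `wobble` (all %).
#' @export
varvel_metrics <- function(pe) {
  if (!length(pe)) stop("empty performance-error series", call. = FALSE)
  mdpe <- stats::median(pe)
  tibble::tibble(
    mdpe = mdpe,
    mdape = stats::median(abs(pe)),
    wobble = stats::median(abs(pe - mdpe))
  )
}

#' Effectiveness and resuscitation effectiveness
#'
#' Effectiveness is the percentage of samples with MAP within `band` mmHg of
#' the target (both sides); resuscitation effectiveness penalizes only
#' undershoot: the percentage of samples with MAP no more than `band` mmHg
#' below the target. Boundaries are inclusive.
#'
#' @param trace tibble with `map_mmHg` and `target_mmHg`.
#' @param band half-width of the band, mmHg.
#' @return one-row tibble with `effectiveness` and
#'   `resuscitation_effectiveness` (%).
#' @export
band_metrics <- function(trace, band = 5) {
  check_trace_metrics(trace)
  dev <- trace$map_mmHg - trace$target_mmHg
  tibble::tibble(
    effectiveness = 100 * mean(abs(dev) <= band),
    resuscitation_effectiveness = 100 * mean(dev >= -band)
  )
}

#' Rise time, target overshoot, and areas above/below the target
#'
#' Rise time is the time from `start` until MAP first reaches the target
#' (`NA` if never). Overshoot is the largest positive excursion above the
#' target as a percentage of the target at that sample. Areas are trapezoidal
#' integrals of the positive part of (MAP - target) and, sign-flipped, of
#' (target - MAP), in mmHg*min.
#'
#' @param trace tibble with `time_min`, `map_mmHg`, `target_mmHg`.
#' @param start resuscitation start time, min; defaults to the first sample.
#' @return one-row tibble with `rise_time`, `target_overshoot`, `area_above`,
#'   `area_below`.
#' @export
transient_metrics <- function(trace, start = NULL) {
  check_trace_metrics(trace)
  if (is.null(start)) start <- trace$time_min[1]
  at <- which(trace$map_mmHg >= trace$target_mmHg & trace$time_min >= start)
  rise <- if (length(at)) trace$time_min[at[1]] - start else NA_real_
  over <- max(0, max((trace$map_mmHg - trace$target_mmHg) / trace$target_mmHg))
  dev <- trace$map_mmHg - trace$target_mmHg
  tibble::tibble(
    rise_time = rise,
    target_overshoot = 100 * over,
    area_above = pracma::trapz(trace$time_min, pmax(dev, 0)),
    area_below = -pracma::trapz(trace$time_min, pmax(-dev, 0))
  )
}

#' Median, mean, and variability of the infusion rate
#'
#' Computed over all event samples, zeros included; variability is the sample
#' standard deviation (n - 1), reported as 0 for a single sample.
#'
#' @param rates infusion-rate series, mL/min.
#' @return one-row tibble with `median_infusion`, `mean_infusion`,
#'   `infusion_variability`.
#' @export
infusion_stats <- function(rates) {
  if (!length(rates)) stop("empty infusion-rate series", call. = FALSE)
  tibble::tibble(
    median_infusion = stats::median(rates),
    mean_infusion = mean(rates),
    infusion_variability = if (length(rates) > 1) stats::sd(rates) else 0
  )
}

#' Twelve-metric scorecard for one resuscitation event
#'
#' @param trace tibble with `time_min`, `map_mmHg`, `target_mmHg` and
#'   `infusion_mL_min` covering the event (resuscitation start through
#'   maintenance end).
#' @param start resuscitation start time, min; defaults to the first sample.
#' @param band effectiveness band half-width, mmHg.
#' @return a one-row tibble of class `metrics_report` with columns `mdpe`,
#'   `mdape`, `wobble`, `effectiveness`, `resuscitation_effectiveness`,
#'   `target_overshoot`, `area_above`, `area_below`, `rise_time`,
#'   `median_infusion`, `mean_infusion`, `infusion_variability`.
#' @export
event_metrics <- function(trace, start = NULL, band = 5) {
  check_trace_metrics(trace)
  if (!"infusion_mL_min" %in% names(trace)) {
    stop("trace is missing column(s): infusion_mL_min", call. = FALSE)
  }
  pe <- performance_error(trace)$pe_pct
  out <- dplyr::bind_cols(
    varvel_metrics(pe),
    band_metrics(trace, band),
    transient_metrics(trace, start),
    infusion_stats(trace$infusion_mL_min)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

metric_order <- c(
  "mdpe", "mdape", "wobble", "effectiveness", "resuscitation_effectiveness",
  "target_overshoot", "area_above", "area_below", "rise_time",
  "median_infusion", "mean_infusion", "infusion_variability"
)

ratio_arrow <- function(r) {
  if (!is.finite(r)) return("")
  if (r >= 1.5) "↑"          # well above 1
  else if (r > 1) "↗"
  else if (r == 1) "→"
  else if (r > 0.5) "↘"
  else "↓"                   # at or below 0.5, or negative
}

#' Two-event ratio report
#'
#' Per metric, the ratio of the first-event value to the second-event value,
#' rounded to two decimals, with a direction glyph keyed to the ratio's
#' magnitude relative to 1. A zero denominator yields a flagged (NA) ratio
#' rather than an error.
#'
#' @param report_event1,report_event2 `metrics_report` rows (see
#'   [event_metrics()]).
#' @return tibble with `metric`, `event1`, `event2`, `ratio`, `arrow`.
#' @export
ratio_table <- function(report_event1, report_event2) {
  stopifnot(all(metric_order %in% names(report_event1)),
            all(metric_order %in% names(report_event2)))
  e1 <- as.numeric(report_event1[1, metric_order])
  e2 <- as.numeric(report_event2[1, metric_order])
  ratio <- ifelse(e2 == 0, NA_real_, round(e1 / e2, 2))
  tibble::tibble(
    metric = metric_order, event1 = e1, event2 = e2, ratio = ratio,
    arrow = vapply(ratio, ratio_arrow, character(1))
  )
}
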