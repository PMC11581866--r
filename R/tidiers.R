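# broom-style tidiers for simulation results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a protocol result into long-format event metrics
#'
#' @param x a `protocol_result`.
#' @param ... unused.
#' @return tibble with `event`, `metric`, `value`.
#' @method tidy protocol_result
#' @export
tidy.protocol_result <- function(x, ...) {
  if (is.null(x$metrics)) {
    return(tibble::tibble(event = integer(0), metric = character(0),
                          value = numeric(0)))
  }
  tidyr::pivot_longer(x$metrics, -"event", names_to = "metric",
                      values_to = "value")[, c("event", "metric", "value")]
}

#' One-row summary of a protocol run
#'
#' @param x a `protocol_result`.
#' @param ... unused.
#' @return one-row tibble: durations, hold outcomes, per-event infused
#'   volumes, and outcome flags.
#' @method glance protocol_result
#' @export
glance.protocol_result <- function(x, ...) {
  vol_ev <- function(nev) {
    v <- x$volumes[x$volumes$event == nev, , drop = FALSE]
    if (is.null(v) || !nrow(v)) NA_real_ else sum(v$volume_mL)
  }
  tibble::tibble(
    duration_min = max(x$trace$time_min),
    hold1_min = x$holds$first,
    hold1_reason = x$holds$first_reason,
    hold2_min = x$holds$second_realized,
    volume_event1_mL = vol_ev(1),
    volume_event2_mL = vol_ev(2),
    target_reached_1 = x$flags$target_reached_1,
    target_reached_2 = x$flags$target_reached_2,
    safety_engaged = x$flags$safety_engaged_1 || x$flags$safety_engaged_2,
    alive = x$flags$alive,
    seed = x$seed
  )
}

#' Tidy a metrics report into long format
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return tibble with `metric` and `value`.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(metric = metric_order, value = as.numeric(x[1, metric_order]))
}

#' Per-subject cohort tibble
#'
#' @param x a `cohort_result`.
#' @param ... unused.
#' @return the per-subject summary tibble.
#' @method tidy cohort_result
#' @export
tidy.cohort_result <- function(x, ...) x$subjects

#' Pooled cohort summary
#'
#' @param x a `cohort_result`.
#' @param ... unused.
#' @return one-row tibble with pooled lactate-slope mean and SD.
#' @method glance cohort_result
#' @export
glance.cohort_result <- function(x, ...) {
  pooled <- x$summary$lactate[x$summary$lactate$anesthetic == "pooled", ]
  tibble::tibble(
    n = pooled$n,
    lactate_slope_mean = pooled$mean_slope,
    lactate_slope_sd = pooled$sd_slope,
    base_seed = x$base_seed
  )
}
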