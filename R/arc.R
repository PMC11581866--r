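# Adaptive resuscitation controller: sliding-window pressure-volume
# responsiveness estimation, pace-driven flow-rate law, CVP safety rule.

#' Adaptive resuscitation controller configuration
#'
#' @param target_map resuscitation target MAP, mmHg.
#' @param pace desired MAP rise rate, mmHg/min.
#' @param control_interval seconds between rate updates.
#' @param regression_window seconds of (volume, MAP) history used by the
#'   responsiveness regression.
#' @param filter_window seconds of raw samples pooled by the pressure filter.
#' @param q_min,q_max pump rate bounds, mL/min.
#' @param deadband mmHg below target: once at target, infusion resumes only
#'   when MAP falls more than `deadband` below the active target.
#' @param slope_floor minimum usable responsiveness, mmHg/mL; estimates below
#'   it are treated as fluid non-responsiveness and clamped.
#' @param bootstrap_slope slope assumed before any usable infusion history.
#' @param min_dv minimum volume span (mL) in the window for a regression.
#' @param cvp_threshold CVP at or above which the safety rule engages, mmHg.
#' @param target_decrement step size of iterative target reductions, mmHg.
#' @param decrement_interval minutes between successive reductions.
#' @param target_floor hard lower bound on the active target, mmHg.
#' @param stabilization_duration minutes at target before maintenance begins.
#' @param maintenance_duration minutes of maintenance after stabilization.
#' @return an `arc_config` object.
#' @export
arc_config <- function(target_map = 65, pace = 6, control_interval = 10,
                       regression_window = 180, filter_window = 10,
                       q_min = 0, q_max = 250, deadband = 2,
                       slope_floor = 0.005, bootstrap_slope = 0.03,
                       min_dv = 5, cvp_threshold = 15, target_decrement = 2,
                       decrement_interval = 5, target_floor = 40,
                       stabilization_duration = 10, maintenance_duration = 120) {
  cfg <- as.list(environment())
  stopifnot(
    "pace must be > 0" = cfg$pace > 0,
    "pump bounds must satisfy 0 <= q_min < q_max" =
      cfg$q_min >= 0 && cfg$q_min < cfg$q_max,
    "deadband must be >= 0" = cfg$deadband >= 0,
    "target_decrement must be > 0" = cfg$target_decrement > 0,
    "slope_floor must be > 0" = cfg$slope_floor > 0,
    "control_interval must be > 0" = cfg$control_interval > 0,
    "regression_window must cover at least two control ticks" =
      cfg$regression_window >= 2 * cfg$control_interval
  )
  structure(cfg, class = "arc_config")
}

#' Fresh controller state for one resuscitation event
#'
#' @param config an `arc_config`.
#' @param baseline_map_reference the subject's own baseline MAP, mmHg; the
#'   first safety action lowers the active target to this value.
#' @param fluid infusate the event starts on.
#' @return an `arc_state` object.
#' @export
new_arc_state <- function(config, baseline_map_reference,
                          fluid = c("whole_blood", "crystalloid")) {
  fluid <- match.arg(fluid)
  structure(list(
    active_target = config$target_map,
    h_time = numeric(0),    # min
    h_volume = numeric(0),  # cumulative infused, mL
    h_map = numeric(0),     # filtered MAP, mmHg
    phase = "resuscitation",
    fluid = fluid,
    starting_fluid = fluid,
    infusing = TRUE,        # hysteresis engagement flag
    safety_engaged = FALSE,
    last_decrement_time = -Inf,
    baseline_map_reference = baseline_map_reference,
    attained_time = NA_real_,
    maintenance_start = NA_real_
  ), class = "arc_state")
}

#' Robust moving filter for the arterial pressure channel
#'
#' Median of the samples in the window after rejecting artifacts, i.e.
#' samples deviating more than `reject` mmHg from the window median (blood
#' draws and similar transients).
#'
#' @param samples raw MAP samples over the filter window, mmHg.
#' @param reject artifact-rejection threshold, mmHg.
#' @return the filtered MAP, mmHg.
#' @export
filter_pressure <- function(samples, reject = 20) {
  samples <- samples[is.finite(samples)]
  if (!length(samples)) stop("filter_pressure: empty sample window", call. = FALSE)
  med <- stats::median(samples)
  kept <- samples[abs(samples - med) <= reject]
  if (!length(kept)) kept <- samples
  stats::median(kept)
}

#' Estimate pressure-volume responsiveness from infusion history
#'
#' Ordinary least-squares slope of filtered MAP against cumulative infused
#' volume over the trailing regression window. When the window holds fewer
#' than two distinct volume points, or spans less than `min_dv` mL, the
#' bootstrap slope is returned so the first command is finite.
#'
#' @param history data frame (or tibble) with columns `time_min`,
#'   `volume_ml`, `map_mmhg`, in increasing time order.
#' @param config an `arc_config`.
#' @return slope in mmHg/mL.
#' @export
estimate_responsiveness <- function(history, config = arc_config()) {
  n <- nrow(history)
  if (is.null(n) || n < 2) return(config$bootstrap_slope)
  cutoff <- history$time_min[n] - config$regression_window / 60
  keep <- history$time_min >= cutoff - 1e-9
  v <- history$volume_ml[keep]
  m <- history$map_mmhg[keep]
  if (length(unique(v)) < 2 || diff(range(v)) < config$min_dv) {
    return(config$bootstrap_slope)
  }
  # simple-regression normal equation in covariance form
  stats::cov(v, m) / stats::var(v)
}

#' Volume still needed to reach the active target
#'
#' @param map current (filtered) MAP, mmHg.
#' @param active_target active target MAP, mmHg.
#' @param slope responsiveness, mmHg/mL; must be positive.
#' @return volume in mL, never negative.
#' @export
volume_to_target <- function(map, active_target, slope) {
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  pmax(0, (active_target - map) / slope)
}

#' Pace-driven infusion rate law
#'
#' The commanded rate is the configured pace divided by the responsiveness
#' estimate (clamped to at least `slope_floor`), bounded to the pump range.
#' Infusion is off when MAP is within the deadband of (or above) the active
#' target; a stateful caller may pass its own hysteresis `engaged` flag
#' instead.
#'
#' @param slope responsiveness estimate, mmHg/mL.
#' @param map current filtered MAP, mmHg.
#' @param active_target active target MAP, mmHg.
#' @param config an `arc_config`.
#' @param engaged optional logical overriding the stateless deadband rule.
#' @return commanded rate, mL/min.
#' @export
compute_rate <- function(slope, map, active_target, config = arc_config(),
                         engaged = NULL) {
  if (is.null(engaged)) engaged <- map < active_target - config$deadband
  if (!engaged) return(0)
  s <- max(slope, config$slope_floor)
  min(config$q_max, max(config$q_min, config$pace / s))
}

#' CVP safety rule
#'
#' The first time CVP reaches the threshold, the active target drops to the
#' subject's baseline MAP (if lower). While CVP stays at or above the
#' threshold, the target is further reduced by `target_decrement` every
#' `decrement_interval` minutes, never below `target_floor`.
#'
#' @param cvp current CVP, mmHg.
#' @param arc_state an `arc_state`.
#' @param config an `arc_config`.
#' @param now current time, min.
#' @return the updated `arc_state`.
#' @export
safety_update <- function(cvp, arc_state, config = arc_config(), now = 0) {
  if (cvp < config$cvp_threshold) return(arc_state)
  if (!arc_state$safety_engaged) {
    arc_state$safety_engaged <- TRUE
    arc_state$active_target <- max(
      config$target_floor,
      min(arc_state$active_target, arc_state$baseline_map_reference)
    )
    arc_state$last_decrement_time <- now
  } else if (now - arc_state$last_decrement_time >= config$decrement_interval) {
    arc_state$active_target <- max(
      config$target_floor,
      arc_state$active_target - config$target_decrement
    )
    arc_state$last_decrement_time <- now
  }
  arc_state
}

#' One control tick of the adaptive resuscitation controller
#'
#' Filters the raw MAP samples gathered since the previous tick, applies the
#' CVP safety rule, appends (cumulative volume, filtered MAP) to the history,
#' re-estimates responsiveness, and emits the pump command. Phase transitions:
#' resuscitation becomes stabilization at the first tick with filtered MAP at
#' or above the active target; stabilization becomes maintenance after
#' `stabilization_duration` minutes, switching the infusate to crystalloid
#' when the event began on whole blood.
#'
#' @param arc_state an `arc_state`.
#' @param map_samples raw MAP samples observed since the previous tick, mmHg.
#' @param cvp current CVP, mmHg.
#' @param cumulative_volume cumulative infused volume for this event, mL.
#' @param config an `arc_config`.
#' @param now current time, min; must exceed the last history timestamp.
#' @param source_hct hematocrit to stamp on whole-blood commands.
#' @return a list with `command` (a `pump_command`), `state` (updated
#'   `arc_state`), `filtered_map` and `slope`.
#' @export
arc_step <- function(arc_state, map_samples, cvp, cumulative_volume,
                     config = arc_config(), now, source_hct = NA_real_) {
  n <- length(arc_state$h_time)
  if (n > 0 && now <= arc_state$h_time[n]) {
    stop("arc_step: out-of-order timestamp", call. = FALSE)
  }
  fmap <- filter_pressure(map_samples)
  arc_state <- safety_update(cvp, arc_state, config, now)

  arc_state$h_time <- c(arc_state$h_time, now)
  arc_state$h_volume <- c(arc_state$h_volume, cumulative_volume)
  arc_state$h_map <- c(arc_state$h_map, fmap)

  # hysteresis: stop at the target, resume below target - deadband
  if (fmap >= arc_state$active_target) {
    arc_state$infusing <- FALSE
    if (arc_state$phase == "resuscitation") {
      arc_state$phase <- "stabilization"
      arc_state$attained_time <- now
    }
  } else if (fmap < arc_state$active_target - config$deadband) {
    arc_state$infusing <- TRUE
  }

  if (arc_state$phase == "stabilization" &&
      now - arc_state$attained_time >= config$stabilization_duration) {
    arc_state$phase <- "maintenance"
    arc_state$maintenance_start <- now
    if (arc_state$starting_fluid == "whole_blood") arc_state$fluid <- "crystalloid"
  }

  slope <- estimate_responsiveness(
    data.frame(time_min = arc_state$h_time, volume_ml = arc_state$h_volume,
               map_mmhg = arc_state$h_map),
    config
  )
  rate <- compute_rate(slope, fmap, arc_state$active_target, config,
                       engaged = arc_state$infusing)
  cmd <- pump_command(
    rate, arc_state$fluid,
    source_hct = if (arc_state$fluid == "whole_blood") source_hct else NA_real_
  )
  list(command = cmd, state = arc_state, filtered_map = fmap, slope = slope)
}
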