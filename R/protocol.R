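# Protocol orchestration: the two-event hemorrhage/resuscitation timeline,
# per-subject runs and cohort aggregation, on top of a shared closed-loop
# simulation engine.

#' Protocol configuration
#'
#' @param hold_lactate_threshold_1 lactate (mmol/L) that ends the first
#'   hypovolemic hold.
#' @param hold_max_duration maximum first-hold duration, min.
#' @param hold_lactate_cap_2 lactate cap that shortens the second hold, mmol/L.
#' @param lactate_sampling_interval minutes between lactate draws during holds.
#' @param maintenance_lactate_interval minutes between draws during
#'   maintenance (first draw right after stabilization).
#' @param baseline_duration minutes of baseline recording before the first
#'   hemorrhage (instrumentation and surgical preparation collapsed into one
#'   stabilization phase).
#' @param hemorrhage_timeout guard on the time allowed to reach the
#'   hypotensive target, min.
#' @param resuscitation_timeout guard on the time allowed to attain the
#'   resuscitation target, min.
#' @param dt simulation step, min (default one second).
#' @param pump_max hard pump-rate limit used by the subject model, mL/min.
#' @return a `protocol_config` object.
#' @export
protocol_config <- function(hold_lactate_threshold_1 = 4, hold_max_duration = 90,
                            hold_lactate_cap_2 = 6,
                            lactate_sampling_interval = 10,
                            maintenance_lactate_interval = 60,
                            baseline_duration = 30, hemorrhage_timeout = 120,
                            resuscitation_timeout = 90, dt = 1 / 60,
                            pump_max = 600) {
  stopifnot(
    "lactate thresholds must be positive" =
      hold_lactate_threshold_1 > 0 && hold_lactate_cap_2 > 0,
    "the second-hold cap must exceed the first-hold threshold" =
      hold_lactate_cap_2 > hold_lactate_threshold_1,
    "dt must be positive" = dt > 0
  )
  structure(as.list(environment()), class = "protocol_config")
}

#' Shock criterion for the first hypovolemic hold
#'
#' Met at the first lactate reading at or above the threshold, or once the
#' elapsed hold reaches the maximum duration, whichever happens first.
#'
#' @param readings tibble/data frame with columns `time_min` and `lactate`.
#' @param threshold lactate threshold, mmol/L.
#' @param max_duration maximum hold duration, min.
#' @param hold_start hold start time, min.
#' @return a list with `met` (logical), `reason` (`"lactate"`, `"timeout"` or
#'   `NA`), and `time` (min, `NA` when not met).
#' @export
shock_criterion <- function(readings, threshold = 4, max_duration = 90,
                            hold_start = 0) {
  hit <- which(readings$lactate >= threshold)
  if (length(hit)) {
    return(list(met = TRUE, reason = "lactate", time = readings$time_min[hit[1]]))
  }
  elapsed <- if (nrow(readings)) max(readings$time_min) - hold_start else 0
  if (elapsed >= max_duration) {
    return(list(met = TRUE, reason = "timeout", time = hold_start + max_duration))
  }
  list(met = FALSE, reason = NA_character_, time = NA_real_)
}

# ---------------------------------------------------------------------------
# Shared closed-loop simulation engine. One call simulates one phase (or a
# controller-defined run of phases) at fixed dt, recording a 1-per-step trace.
# `controller` is NULL (no commands), an environment made by
# make_autobleed_controller(), or one made by make_arc_controller().
sim_phase <- function(params, state, controller = NULL, bag = NULL,
                      max_duration, dt = 1 / 60, pump_max = 600,
                      lactate_times = numeric(0), stop_fn = NULL,
                      phase_label = "phase") {
  n_max <- ceiling(max_duration / dt) + 1L
  col <- function(x = NA_real_) rep(x, n_max)
  tr_time <- col(); tr_map <- col(); tr_map_raw <- col(); tr_cvp <- col()
  tr_lac <- col(); tr_hct <- col(); tr_inf <- col(); tr_bagv <- col()
  tr_tgt <- col(); tr_lac_true <- col()
  tr_fluid <- rep(NA_character_, n_max); tr_phase <- rep(NA_character_, n_max)

  fw_n <- 10L
  ctrl_every <- 10L
  if (!is.null(controller)) {
    fw_n <- max(1L, as.integer(round(controller$config$filter_window / (dt * 60))))
    ctrl_every <- max(1L, as.integer(round(controller$config$control_interval / (dt * 60))))
  }
  buf <- rep(state$map, fw_n)
  bi <- 0L

  command <- pump_command(0, "whole_blood")
  readings_t <- numeric(0); readings_v <- numeric(0)
  lp <- 1L
  # draws scheduled at (or before) phase entry are taken immediately, so the
  # reading at a hold's start reflects the state at that instant
  while (lp <= length(lactate_times) && lactate_times[lp] <= state$time + 1e-9) {
    readings_t <- c(readings_t, lactate_times[lp])
    readings_v <- c(readings_v, state$lactate)
    lp <- lp + 1L
  }
  stop_reason <- NA_character_
  i <- 0L

  while (i < n_max - 1L) {
    i <- i + 1L
    now <- state$time
    vit <- sample_vitals(state, params)
    bi <- bi %% fw_n + 1L
    buf[bi] <- vit$map
    fmap <- filter_pressure(buf)

    if (!is.null(controller) && (i - 1L) %% ctrl_every == 0L) {
      out <- controller$tick(buf, vit$cvp, now, bag)
      command <- out$command
      bag <- out$bag
    }

    # clamp whole-blood infusion to what the bag holds
    cmd_eff <- command
    if (cmd_eff$rate > 0 && cmd_eff$fluid == "whole_blood" && !is.null(bag)) {
      avail <- bag_volume(bag)
      vol <- cmd_eff$rate * dt
      if (avail <= 1e-9) {
        if (!is.null(controller) && identical(controller$type, "arc")) {
          controller$switch_to_crystalloid()
          cmd_eff <- pump_command(cmd_eff$rate, "crystalloid")
          command <- cmd_eff
        } else {
          cmd_eff <- pump_command(0, "whole_blood")
          command <- cmd_eff
        }
      } else if (vol > avail) {
        cmd_eff <- pump_command(avail / dt, "whole_blood", source_hct = bag$hct)
      }
    }

    # bag accounting for the fluid actually moved this step
    if (!is.null(bag)) {
      if (cmd_eff$rate < 0) {
        w <- -cmd_eff$rate * dt
        bag <- bag_update(bag, withdrawn_ml = w, subject_hct = state$hct,
                          cpda_ml = w / controller$config$cpda_ratio)
      } else if (cmd_eff$rate > 0 && cmd_eff$fluid == "whole_blood") {
        bag <- bag_update(bag, reinfused_ml = cmd_eff$rate * dt)
      }
    }

    if (!is.null(controller)) controller$account(cmd_eff, dt)
    state <- step_subject(params, state, cmd_eff, dt, pump_max = pump_max)

    # scheduled lactate draws
    lac_now <- NA_real_
    while (lp <= length(lactate_times) && lactate_times[lp] <= state$time + 1e-9) {
      lac_now <- state$lactate
      readings_t <- c(readings_t, lactate_times[lp])
      readings_v <- c(readings_v, state$lactate)
      lp <- lp + 1L
    }

    tr_time[i] <- state$time
    tr_map[i] <- fmap
    tr_map_raw[i] <- vit$map
    tr_cvp[i] <- vit$cvp
    tr_lac[i] <- lac_now
    tr_lac_true[i] <- state$lactate
    tr_hct[i] <- state$hct
    tr_inf[i] <- cmd_eff$rate
    tr_fluid[i] <- cmd_eff$fluid
    tr_bagv[i] <- if (is.null(bag)) NA_real_ else bag_volume(bag)
    tr_tgt[i] <- if (is.null(controller)) NA_real_ else controller$active_target()
    tr_phase[i] <- if (!is.null(controller) && !is.null(controller$phase_label)) {
      controller$phase_label()
    } else phase_label

    if (!state$alive) { stop_reason <- "death"; break }
    if (!is.null(stop_fn)) {
      r <- stop_fn(list(
        state = state, fmap = fmap, now = state$time,
        readings = list(time_min = readings_t, lactate = readings_v),
        controller = controller
      ))
      if (!is.null(r)) { stop_reason <- r; break }
    }
  }
  if (is.na(stop_reason) && i >= n_max - 1L) stop_reason <- "duration"

  keep <- seq_len(i)
  trace <- tibble::tibble(
    time_min = tr_time[keep], map_mmHg = tr_map[keep],
    map_raw_mmHg = tr_map_raw[keep], cvp_mmHg = tr_cvp[keep],
    lactate_mmol_L = tr_lac[keep], lactate_true = tr_lac_true[keep],
    hct_frac = tr_hct[keep], infusion_mL_min = tr_inf[keep],
    fluid = tr_fluid[keep], bag_volume_mL = tr_bagv[keep],
    target_mmHg = tr_tgt[keep], phase = tr_phase[keep]
  )
  list(trace = trace, state = state, bag = bag, controller = controller,
       readings = tibble::tibble(time_min = readings_t, lactate = readings_v),
       stop_reason = stop_reason)
}

# Controller wrapper environments -------------------------------------------

make_autobleed_controller <- function(config, phase_label = "hemorrhage") {
  env <- new.env(parent = emptyenv())
  env$type <- "autobleed"
  env$config <- config
  env$ab_state <- new_autobleed_state(config)
  env$log_time <- numeric(0); env$log_rate <- numeric(0)
  env$log_fmap <- numeric(0); env$log_cpda <- numeric(0)
  env$log_bagv <- numeric(0); env$log_baghct <- numeric(0)
  env$label <- phase_label
  env$tick <- function(buf, cvp, now, bag) {
    out <- autobleed_step(env$ab_state, buf, env$config, bag, engaged = TRUE)
    env$ab_state <- out$state
    env$log_time <- c(env$log_time, now)
    env$log_rate <- c(env$log_rate, out$command$rate)
    env$log_fmap <- c(env$log_fmap, out$filtered_map)
    env$log_cpda <- c(env$log_cpda, out$cpda_rate_ml_min)
    env$log_bagv <- c(env$log_bagv, bag_volume(out$bag))
    env$log_baghct <- c(env$log_baghct, out$bag$hct)
    list(command = out$command, bag = out$bag)
  }
  env$account <- function(cmd, dt) invisible(NULL)
  env$active_target <- function() env$config$target_map
  env$phase_label <- NULL  # caller-supplied label is used
  env$decisions <- function() tibble::tibble(
    time_min = env$log_time, phase = env$label,
    active_target_mmHg = env$config$target_map,
    filtered_map_mmHg = env$log_fmap,
    commanded_rate_mL_min = env$log_rate, fluid = "whole_blood",
    cpda_rate_mL_min = env$log_cpda, bag_volume_mL = env$log_bagv,
    bag_hct_frac = env$log_baghct
  )
  env
}

make_arc_controller <- function(config, baseline_map_reference,
                                fluid = "whole_blood", event = 1L) {
  env <- new.env(parent = emptyenv())
  env$type <- "arc"
  env$config <- config
  env$arc_state <- new_arc_state(config, baseline_map_reference, fluid)
  env$cum_infused <- 0
  env$event <- event
  env$log_time <- numeric(0); env$log_target <- numeric(0)
  env$log_slope <- numeric(0); env$log_rate <- numeric(0)
  env$log_fluid <- character(0); env$log_safety <- logical(0)
  env$tick <- function(buf, cvp, now, bag) {
    src_hct <- if (!is.null(bag)) bag$hct else env$fallback_source_hct
    out <- arc_step(env$arc_state, buf, cvp, env$cum_infused, env$config, now,
                    source_hct = src_hct)
    env$arc_state <- out$state
    env$log_time <- c(env$log_time, now)
    env$log_target <- c(env$log_target, out$state$active_target)
    env$log_slope <- c(env$log_slope, out$slope)
    env$log_rate <- c(env$log_rate, out$command$rate)
    env$log_fluid <- c(env$log_fluid, out$command$fluid)
    env$log_safety <- c(env$log_safety, out$state$safety_engaged)
    list(command = out$command, bag = bag)
  }
  env$fallback_source_hct <- NA_real_
  env$account <- function(cmd, dt) {
    if (cmd$rate > 0) env$cum_infused <- env$cum_infused + cmd$rate * dt
  }
  env$switch_to_crystalloid <- function() {
    env$arc_state$fluid <- "crystalloid"
  }
  env$active_target <- function() env$arc_state$active_target
  env$phase_label <- function() paste0(env$arc_state$phase, env$event)
  env$decisions <- function() tibble::tibble(
    time_min = env$log_time, phase = paste0("event", env$event),
    active_target_mmHg = env$log_target, slope_mmHg_per_mL = env$log_slope,
    commanded_rate_mL_min = env$log_rate, fluid = env$log_fluid,
    safety_engaged = env$log_safety
  )
  env
}

# Public session runners -----------------------------------------------------

#' Run an AutoBleed session on a synthetic subject
#'
#' Engages the hemorrhage controller for up to `duration` minutes (hemorrhage
#' plus hypovolemic hold), with optional scheduled lactate draws and an
#' optional early-stop rule.
#'
#' @param params a `subject_params`.
#' @param state starting `subject_state` (defaults to the subject's baseline).
#' @param config an `autobleed_config`.
#' @param bag starting `blood_bag`.
#' @param duration maximum duration, min.
#' @param dt simulation step, min.
#' @param seed optional seed applied before the run; leave `NULL` to continue
#'   the current RNG stream.
#' @param lactate_times absolute times (min) of scheduled lactate draws.
#' @param stop_fn optional function of a context list (`state`, `fmap`, `now`,
#'   `readings`) returning `NULL` to continue or a character stop reason.
#' @param phase_label label stamped on the trace rows.
#' @return list with `trace`, `decisions`, `state`, `bag`, `readings`,
#'   `stop_reason`.
#' @export
run_autobleed_session <- function(params, state = new_subject_state(params),
                                  config = autobleed_config(),
                                  bag = new_blood_bag(), duration = 60,
                                  dt = 1 / 60, seed = NULL,
                                  lactate_times = numeric(0), stop_fn = NULL,
                                  phase_label = "hemorrhage") {
  if (!is.null(seed)) set.seed(seed)
  ctrl <- make_autobleed_controller(config, phase_label)
  out <- sim_phase(params, state, ctrl, bag, max_duration = duration, dt = dt,
                   lactate_times = lactate_times, stop_fn = stop_fn,
                   phase_label = phase_label)
  list(trace = out$trace, decisions = ctrl$decisions(), state = out$state,
       bag = out$bag, readings = out$readings, stop_reason = out$stop_reason)
}

#' Run an adaptive-resuscitation-controller session on a synthetic subject
#'
#' Runs the controller from resuscitation through stabilization and
#' maintenance (or until `duration` elapses). Whole blood is drawn from `bag`
#' when one is given; otherwise an unlimited source at `source_hct` is
#' assumed.
#'
#' @inheritParams run_autobleed_session
#' @param config an `arc_config`.
#' @param fluid infusate the event starts on.
#' @param source_hct hematocrit of the whole-blood source when `bag` is NULL.
#' @param stop_fn optional early-stop rule; the context list additionally
#'   carries `controller` (whose `$arc_state` holds phase and timers).
#' @return list with `trace`, `decisions`, `state`, `bag`, `arc_state`,
#'   `readings`, `stop_reason`.
#' @export
run_arc_session <- function(params, state, config = arc_config(), bag = NULL,
                            fluid = c("whole_blood", "crystalloid"),
                            duration = 240, dt = 1 / 60, seed = NULL,
                            source_hct = params$baseline_hct,
                            lactate_times = numeric(0), stop_fn = NULL) {
  fluid <- match.arg(fluid)
  if (!is.null(seed)) set.seed(seed)
  ctrl <- make_arc_controller(config, baseline_map_reference = params$baseline_map,
                              fluid = fluid)
  ctrl$fallback_source_hct <- source_hct
  out <- sim_phase(params, state, ctrl, bag, max_duration = duration, dt = dt,
                   lactate_times = lactate_times, stop_fn = stop_fn)
  list(trace = out$trace, decisions = ctrl$decisions(), state = out$state,
       bag = out$bag, arc_state = ctrl$arc_state, readings = out$readings,
       stop_reason = out$stop_reason)
}

# ---------------------------------------------------------------------------

#' Run the full two-event hemorrhage/resuscitation protocol
#'
#' Executes, in order: baseline recording; AutoBleed hemorrhage to the
#' hypotensive target and hypovolemic hold (ended by the lactate threshold or
#' the maximum duration); whole-blood resuscitation by the adaptive controller
#' with 10-min stabilization and 120-min crystalloid maintenance; a second
#' matched hemorrhage and hold (shortened if lactate reaches the cap); and a
#' crystalloid-only resuscitation with stabilization and maintenance.
#'
#' @param params a `subject_params`.
#' @param arc an `arc_config`.
#' @param autobleed an `autobleed_config`.
#' @param protocol a `protocol_config`.
#' @param seed integer seed for all stochastic draws in the run.
#' @param stop_after optional early exit: `"hold1"` stops after the first
#'   hypovolemic hold (used for lactate-kinetics studies), `"event1"` after
#'   the first maintenance period.
#' @return a `protocol_result`: list with `trace` (all phases), `decisions`,
#'   `events`, `metrics` (one row per resuscitation event), `holds`,
#'   `volumes`, `flags`, `lactate_readings`, plus the configs and seed.
#' @export
run_protocol <- function(params, arc = arc_config(),
                         autobleed = autobleed_config(),
                         protocol = protocol_config(), seed = 1,
                         stop_after = NULL) {
  if (!is.null(stop_after)) stop_after <- match.arg(stop_after, c("hold1", "event1"))
  set.seed(seed)
  dt <- protocol$dt
  state <- new_subject_state(params)
  bag <- new_blood_bag()
  traces <- list(); decisions <- list()
  events <- list(); readings <- list()
  ev <- function(name, time) events[[length(events) + 1L]] <<-
    tibble::tibble(event = name, time_min = time)

  ev("protocol_start", 0)

  # --- baseline ---
  out <- sim_phase(params, state, controller = NULL, bag = bag,
                   max_duration = protocol$baseline_duration, dt = dt,
                   pump_max = protocol$pump_max, phase_label = "baseline")
  traces$baseline <- out$trace; state <- out$state

  hemorrhage_hold <- function(state, bag, nev, hold_rule) {
    # hemorrhage to the hypotensive target band
    ctrl <- make_autobleed_controller(autobleed, paste0("hemorrhage", nev))
    ev(paste0("hemorrhage", nev, "_start"), state$time)
    out <- sim_phase(params, state, ctrl, bag,
                     max_duration = protocol$hemorrhage_timeout, dt = dt,
                     pump_max = protocol$pump_max,
                     phase_label = paste0("hemorrhage", nev),
                     stop_fn = function(cx) {
                       if (cx$fmap <= autobleed$target_map + autobleed$tolerance)
                         "target_band" else NULL
                     })
    traces[[paste0("hemorrhage", nev)]] <<- out$trace
    state <- out$state; bag <- out$bag
    hold_start <- state$time
    ev(paste0("hold", nev, "_start"), hold_start)

    lt <- seq(hold_start, hold_start + protocol$hold_max_duration,
              by = protocol$lactate_sampling_interval)
    out <- sim_phase(params, state, ctrl, bag,
                     max_duration = hold_rule$max_duration + 1, dt = dt,
                     pump_max = protocol$pump_max,
                     phase_label = paste0("hold", nev),
                     lactate_times = lt,
                     stop_fn = function(cx) {
                       if (length(cx$readings$lactate) &&
                           any(cx$readings$lactate >= hold_rule$lactate_limit))
                         return("lactate")
                       if (cx$now - hold_start >= hold_rule$max_duration)
                         return("max_duration")
                       NULL
                     })
    traces[[paste0("hold", nev)]] <<- out$trace
    decisions[[paste0("autobleed", nev)]] <<- ctrl$decisions()
    readings[[paste0("hold", nev)]] <<-
      dplyr::mutate(out$readings, phase = paste0("hold", nev))
    ev(paste0("hold", nev, "_end_", out$stop_reason), out$state$time)
    list(state = out$state, bag = out$bag, hold_start = hold_start,
         hold_end = out$state$time, stop_reason = out$stop_reason)
  }

  resuscitate <- function(state, bag, nev, fluid) {
    ctrl <- make_arc_controller(arc, baseline_map_reference = params$baseline_map,
                                fluid = fluid, event = nev)
    ev(paste0("cacl2_bolus_", nev), state$time)  # event marker only
    ev(paste0("resuscitation", nev, "_start"), state$time)
    event_start <- state$time
    total_guard <- protocol$resuscitation_timeout +
      arc$stabilization_duration + arc$maintenance_duration + 10
    out <- sim_phase(params, state, ctrl, bag, max_duration = total_guard,
                     dt = dt, pump_max = protocol$pump_max,
                     stop_fn = function(cx) {
                       st <- cx$controller$arc_state
                       if (st$phase == "maintenance" &&
                           cx$now - st$maintenance_start >= arc$maintenance_duration)
                         return("maintenance_complete")
                       if (st$phase == "resuscitation" &&
                           cx$now - event_start >= protocol$resuscitation_timeout)
                         return("resuscitation_timeout")
                       NULL
                     })
    st <- ctrl$arc_state
    if (!is.na(st$attained_time)) ev(paste0("target_attained_", nev), st$attained_time)
    if (!is.na(st$maintenance_start)) ev(paste0("maintenance", nev, "_start"), st$maintenance_start)
    ev(paste0("event", nev, "_end"), out$state$time)

    # sparsify maintenance lactate draws from the continuous channel
    tr <- out$trace
    if (!is.na(st$maintenance_start)) {
      draws <- seq(st$maintenance_start, max(tr$time_min),
                   by = protocol$maintenance_lactate_interval)
      idx <- vapply(draws, function(d) which.min(abs(tr$time_min - d)), integer(1))
      tr$lactate_mmol_L[idx] <- tr$lactate_true[idx]
      readings[[paste0("maintenance", nev)]] <<- tibble::tibble(
        time_min = tr$time_min[idx], lactate = tr$lactate_true[idx],
        phase = paste0("maintenance", nev))
    }
    traces[[paste0("event", nev)]] <<- tr
    decisions[[paste0("arc", nev)]] <<- ctrl$decisions()
    list(state = out$state, bag = out$bag, arc_state = st,
         event_start = event_start, stop_reason = out$stop_reason)
  }

  # --- first hemorrhage + hold ---
  h1 <- hemorrhage_hold(state, bag, 1L, list(
    lactate_limit = protocol$hold_lactate_threshold_1,
    max_duration = protocol$hold_max_duration))
  state <- h1$state; bag <- h1$bag
  hold1_duration <- h1$hold_end - h1$hold_start

  if (identical(stop_after, "hold1") || !state$alive) {
    return(finish_protocol(traces, decisions, events, readings, params, arc,
                           autobleed, protocol, seed, state,
                           holds = list(first = hold1_duration,
                                        second_planned = NA_real_,
                                        second_realized = NA_real_,
                                        first_reason = h1$stop_reason,
                                        second_reason = NA_character_),
                           arc_states = list()))
  }

  # --- first resuscitation (whole blood from the bag) ---
  r1 <- resuscitate(state, bag, 1L, "whole_blood")
  state <- r1$state; bag <- r1$bag

  if (identical(stop_after, "event1") || !state$alive) {
    return(finish_protocol(traces, decisions, events, readings, params, arc,
                           autobleed, protocol, seed, state,
                           holds = list(first = hold1_duration,
                                        second_planned = NA_real_,
                                        second_realized = NA_real_,
                                        first_reason = h1$stop_reason,
                                        second_reason = NA_character_),
                           arc_states = list(r1$arc_state)))
  }

  # --- second hemorrhage + matched hold with lactate cap ---
  h2 <- hemorrhage_hold(state, bag, 2L, list(
    lactate_limit = protocol$hold_lactate_cap_2,
    max_duration = hold1_duration))
  state <- h2$state; bag <- h2$bag

  holds <- list(first = hold1_duration, second_planned = hold1_duration,
                second_realized = h2$hold_end - h2$hold_start,
                first_reason = h1$stop_reason, second_reason = h2$stop_reason)

  if (!state$alive) {
    return(finish_protocol(traces, decisions, events, readings, params, arc,
                           autobleed, protocol, seed, state, holds,
                           arc_states = list(r1$arc_state)))
  }

  # --- second resuscitation (crystalloid only) ---
  r2 <- resuscitate(state, bag, 2L, "crystalloid")
  state <- r2$state

  finish_protocol(traces, decisions, events, readings, params, arc, autobleed,
                  protocol, seed, state, holds,
                  arc_states = list(r1$arc_state, r2$arc_state))
}

# Assemble the protocol_result object.
finish_protocol <- function(traces, decisions, events, readings, params, arc,
                            autobleed, protocol, seed, state, holds,
                            arc_states) {
  trace <- dplyr::bind_rows(traces)
  events <- dplyr::bind_rows(events)
  lactate_readings <- if (length(readings)) dplyr::bind_rows(readings) else
    tibble::tibble(time_min = numeric(0), lactate = numeric(0), phase = character(0))

  metrics <- NULL; volumes <- NULL
  for (nev in seq_along(arc_states)) {
    ph <- paste0(c("resuscitation", "stabilization", "maintenance"), nev)
    sl <- trace[trace$phase %in% ph, , drop = FALSE]
    if (!nrow(sl)) next
    m <- event_metrics(sl)
    m$event <- nev
    metrics <- dplyr::bind_rows(metrics, m)
    vols <- sl |>
      dplyr::filter(.data$infusion_mL_min > 0) |>
      dplyr::group_by(.data$fluid) |>
      dplyr::summarise(volume_mL = sum(.data$infusion_mL_min) * protocol$dt,
                       .groups = "drop") |>
      dplyr::mutate(event = nev,
                    mean_rate_mL_min = sum(sl$infusion_mL_min) / nrow(sl))
    volumes <- dplyr::bind_rows(volumes, vols)
  }

  flags <- tibble::tibble(
    alive = state$alive,
    target_reached_1 = length(arc_states) >= 1 && !is.na(arc_states[[1]]$attained_time),
    target_reached_2 = length(arc_states) >= 2 && !is.na(arc_states[[2]]$attained_time),
    safety_engaged_1 = length(arc_states) >= 1 && arc_states[[1]]$safety_engaged,
    safety_engaged_2 = length(arc_states) >= 2 && arc_states[[2]]$safety_engaged,
    hold2_cap_fired = identical(holds$second_reason, "lactate")
  )

  structure(list(
    trace = trace, decisions = decisions, events = events, metrics = metrics,
    holds = holds, volumes = volumes, flags = flags,
    lactate_readings = lactate_readings, final_state = state,
    params = params, arc = arc, autobleed = autobleed, protocol = protocol,
    seed = seed
  ), class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result> ", nrow(x$trace), " samples over ",
      round(max(x$trace$time_min), 1), " min; first hold ",
      round(x$holds$first, 1), " min (", x$holds$first_reason, ")\n", sep = "")
  if (!is.null(x$metrics)) {
    cat("resuscitation events scored:", nrow(x$metrics), "\n")
  }
  invisible(x)
}

#' Ordinary least-squares lactate accumulation slope over hold readings
#'
#' @param readings tibble with `time_min` and `lactate` (the 10-min cadence
#'   draws of one hypovolemic hold).
#' @return slope in mmol/L/hr (`NA` with fewer than two readings).
#' @export
lactate_slope <- function(readings) {
  if (nrow(readings) < 2) return(NA_real_)
  unname(stats::coef(stats::lm(lactate ~ time_min, data = readings))[2]) * 60
}

#' Run a cohort of independently seeded subjects through the protocol
#'
#' @param n cohort size; must equal the sum of the stratum counts.
#' @param ketamine,isoflurane,propofol subjects per anesthetic stratum.
#' @param base_seed integer; subject `i` runs with seed `base_seed + i`.
#' @param overrides subject parameter overrides applied to every subject
#'   (e.g. `list(noise_sd = 0)`).
#' @param jitter relative between-subject parameter jitter (see
#'   [make_subject()]).
#' @param arc,autobleed,protocol controller and protocol configurations.
#' @param stop_after passed to [run_protocol()].
#' @return a `cohort_result`: list with `results` (per-subject
#'   `protocol_result`s), `subjects` (per-subject summary tibble including the
#'   hold-phase lactate slope in mmol/L/hr), and `summary` (per-stratum and
#'   pooled lactate-slope statistics; per-event metric means and SDs when the
#'   full protocol was run).
#' @export
run_cohort <- function(n, ketamine = n, isoflurane = 0, propofol = 0,
                       base_seed = 1, overrides = list(), jitter = 0,
                       arc = arc_config(), autobleed = autobleed_config(),
                       protocol = protocol_config(), stop_after = NULL) {
  stopifnot("n must be >= 1" = n >= 1,
            "stratum counts must sum to n" = ketamine + isoflurane + propofol == n)
  strata <- rep(c("ketamine", "isoflurane", "propofol"),
                c(ketamine, isoflurane, propofol))
  results <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ov <- utils::modifyList(overrides, list(anesthetic = strata[i]))
    subj <- make_subject(ov, seed = base_seed + i, jitter = jitter)
    res <- run_protocol(subj, arc = arc, autobleed = autobleed,
                        protocol = protocol, seed = base_seed + i,
                        stop_after = stop_after)
    results[[i]] <- res
    hold1 <- res$lactate_readings[res$lactate_readings$phase == "hold1", ]
    rows[[i]] <- tibble::tibble(
      subject = i, anesthetic = strata[i], seed = base_seed + i,
      lactate_slope_mmol_L_hr = lactate_slope(hold1),
      hold1_duration_min = res$holds$first,
      hold1_reason = res$holds$first_reason,
      alive = res$final_state$alive
    )
  }
  subjects <- dplyr::bind_rows(rows)

  lac_summary <- subjects |>
    dplyr::group_by(.data$anesthetic) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_slope = mean(.data$lactate_slope_mmol_L_hr, na.rm = TRUE),
      sd_slope = stats::sd(.data$lactate_slope_mmol_L_hr),
      .groups = "drop"
    ) |>
    dplyr::bind_rows(tibble::tibble(
      anesthetic = "pooled", n = n,
      mean_slope = mean(subjects$lactate_slope_mmol_L_hr, na.rm = TRUE),
      sd_slope = stats::sd(subjects$lactate_slope_mmol_L_hr)
    ))

  metrics_summary <- NULL
  all_metrics <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    m <- results[[i]]$metrics
    if (is.null(m)) NULL else dplyr::mutate(m, subject = i)
  }))
  if (!is.null(all_metrics) && nrow(all_metrics)) {
    metrics_summary <- all_metrics |>
      tidyr::pivot_longer(-c("event", "subject"),
                          names_to = "metric", values_to = "value") |>
      dplyr::group_by(.data$event, .data$metric) |>
      dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                       sd = stats::sd(.data$value), .groups = "drop")
  }

  structure(list(results = results, subjects = subjects,
                 summary = list(lactate = lac_summary, metrics = metrics_summary),
                 base_seed = base_seed),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> n =", nrow(x$subjects), "subjects\n")
  print(x$summary$lactate)
  invisible(x)
}
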