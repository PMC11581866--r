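# Synthetic swine hemodynamic model: MAP/CVP/lactate/hematocrit responses to
# hemorrhage and fluid infusion.

#' Default parameter set for the synthetic subject
#'
#' Field-by-field defaults for a ~40 kg swine: 70 mL/kg blood volume, baseline
#' MAP 65 mmHg, and a linear whole-blood pressure-volume response of
#' 0.03 mmHg/mL (so a 1,000 mL bleed spans 65 to 35 mmHg). Crystalloid
#' intravascular retention falls from 0.80 at or below 45 mmHg to 0.25 at or
#' above 65 mmHg, and retained crystalloid leaks back to the interstitium at
#' `leak_rate` per minute per mmHg above the lower knee. Lactate accumulates
#' during ischemia at an anesthetic-stratified rate (4.95 mmol/L/hr ketamine,
#' 2.49 mmol/L/hr isoflurane) and clears, after a lag, at a rate that depends
#' on the infusate (1.0 mmol/L/hr on whole blood, 2.0 mmol/L/hr on
#' crystalloid).
#'
#' @keywords internal
subject_defaults <- function() {
  list(
    weight = 40,                       # kg
    blood_volume_per_kg = 70,          # mL/kg
    baseline_map = 65,                 # mmHg
    baseline_cvp = 5,                  # mmHg
    baseline_lactate = 1.0,            # mmol/L
    baseline_hct = 0.30,               # fraction
    wb_slope = 0.03,                   # mmHg per mL
    crystalloid_retention_max = 0.80,  # fraction at low pressure
    crystalloid_retention_min = 0.25,  # fraction at high pressure
    retention_knee_low = 45,           # mmHg
    retention_knee_high = 65,          # mmHg
    leak_rate = 0.004,                 # /min per mmHg above knee_low
    cvp_volume_gain = 0.004,           # mmHg per mL intravascular deficit/excess
    cvp_interstitial_gain = 0.002,     # mmHg per mL interstitial excess
    lactate_accum_rate = NA_real_,     # mmol/L/hr, set by anesthetic if NA
    lactate_clear_rate_wb = 1.0,       # mmol/L/hr
    lactate_clear_rate_crystalloid = 2.0,  # mmol/L/hr
    clearance_lag = 20,                # min above clearance threshold before clearing
    ischemia_map_threshold = 40,       # mmHg, lactate accumulates below
    clearance_map_threshold = 55,      # mmHg, clearance clock runs at/above
    noise_sd = 2,                      # mmHg additive noise on pressure channels
    anesthetic = "ketamine"
  )
}

# Accumulation rates per anesthetic stratum (mmol/L/hr). The propofol value is
# the pooled cohort rate: that stratum had a single subject and no
# stratum-specific rate.
lactate_rate_by_anesthetic <- c(
  ketamine = 4.95, isoflurane = 2.49, propofol = 3.61
)

validate_subject_params <- function(p) {
  num <- p[setdiff(names(p), "anesthetic")]
  if (!all(vapply(num, function(x) is.numeric(x) && is.finite(x), logical(1)))) {
    bad <- names(num)[!vapply(num, function(x) is.numeric(x) && is.finite(x), logical(1))]
    stop("non-finite subject parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stopifnot(
    "wb_slope must be > 0" = p$wb_slope > 0,
    "retention fractions must satisfy 0 <= min <= max <= 1" =
      p$crystalloid_retention_min >= 0 &&
      p$crystalloid_retention_min <= p$crystalloid_retention_max &&
      p$crystalloid_retention_max <= 1,
    "retention_knee_low must be below retention_knee_high" =
      p$retention_knee_low < p$retention_knee_high,
    "baseline_hct must be in (0, 1)" = p$baseline_hct > 0 && p$baseline_hct < 1,
    "weight and blood_volume_per_kg must be positive" =
      p$weight > 0 && p$blood_volume_per_kg > 0,
    "noise_sd must be >= 0" = p$noise_sd >= 0
  )
  if (!p$anesthetic %in% names(lactate_rate_by_anesthetic)) {
    stop("unknown anesthetic: ", p$anesthetic, call. = FALSE)
  }
  invisible(p)
}

#' Create a synthetic subject parameter set
#'
#' Returns the default virtual-swine parameters, with optional overrides and
#' optional relative Gaussian jitter for cohort variability. The lactate
#' accumulation rate is set by the anesthetic stratum (4.95 mmol/L/hr for
#' ketamine, 2.49 for isoflurane) unless overridden explicitly.
#'
#' @param overrides named list of parameter overrides; unknown names are an error.
#' @param seed integer seed controlling the jitter draws; ignored when
#'   `jitter = 0`.
#' @param jitter relative standard deviation of multiplicative Gaussian jitter
#'   applied to `wb_slope`, `baseline_map`, `baseline_hct` and
#'   `lactate_accum_rate` (0 disables jitter, the default).
#' @return an object of class `subject_params` (a named list).
#' @examples
#' make_subject(list(anesthetic = "isoflurane"))$lactate_accum_rate
#' @export
make_subject <- function(overrides = list(), seed = NULL, jitter = 0) {
  p <- subject_defaults()
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("overrides must be a named list", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown)) {
      stop("unknown subject parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(overrides)] <- overrides
  }
  if (is.na(p$lactate_accum_rate)) {
    if (!p$anesthetic %in% names(lactate_rate_by_anesthetic)) {
      stop("unknown anesthetic: ", p$anesthetic, call. = FALSE)
    }
    p$lactate_accum_rate <- unname(lactate_rate_by_anesthetic[p$anesthetic])
  }
  if (jitter > 0) {
    if (is.null(seed)) stop("jitter requires a seed", call. = FALSE)
    p <- with_preserved_rng(seed, {
      for (f in c("wb_slope", "baseline_map", "baseline_hct", "lactate_accum_rate")) {
        p[[f]] <- p[[f]] * max(0.1, 1 + stats::rnorm(1, 0, jitter))
      }
      p$baseline_hct <- min(p$baseline_hct, 0.95)
      p
    })
  }
  validate_subject_params(p)
  structure(p, class = "subject_params")
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' @export
print.subject_params <- function(x, ...) {
  cat("<subject_params> ", x$weight, "kg ", x$anesthetic,
      " swine; V0 = ", x$weight * x$blood_volume_per_kg, " mL; baseline MAP ",
      x$baseline_map, " mmHg; WB slope ", x$wb_slope, " mmHg/mL\n", sep = "")
  invisible(x)
}

#' Reference (euvolemic) blood volume of a subject, in mL
#' @param params a `subject_params` object.
#' @export
reference_volume <- function(params) params$weight * params$blood_volume_per_kg

#' Initial state of a synthetic subject
#'
#' @param params a `subject_params` object.
#' @return an object of class `subject_state`: evolving hemodynamic state plus
#'   cumulative fluid-bookkeeping counters used by the conservation audit.
#' @export
new_subject_state <- function(params) {
  v0 <- reference_volume(params)
  structure(list(
    time = 0,
    intravascular_volume = v0,
    interstitial_excess = 0,
    crystalloid_volume = 0,             # crystalloid currently intravascular, mL
    rbc_volume = v0 * params$baseline_hct,
    map = params$baseline_map,
    cvp = params$baseline_cvp,
    lactate = params$baseline_lactate,
    hct = params$baseline_hct,
    time_above_clearance_threshold = 0,
    alive = TRUE,
    # conservation-audit counters (mL)
    cum_withdrawn = 0,
    cum_wb_infused = 0,
    cum_crystalloid_retained = 0,
    cum_leaked = 0
  ), class = "subject_state")
}

#' Mean arterial pressure implied by an intravascular volume
#'
#' Linear pressure-volume law: `baseline_map + wb_slope * (V - V0)`, floored
#' at 0 mmHg.
#'
#' @param params a `subject_params` object.
#' @param intravascular_volume volume in mL, must be positive.
#' @return MAP in mmHg.
#' @export
map_from_volume <- function(params, intravascular_volume) {
  if (any(intravascular_volume <= 0)) {
    stop("intravascular volume must be positive", call. = FALSE)
  }
  v0 <- reference_volume(params)
  pmax(0, params$baseline_map + params$wb_slope * (intravascular_volume - v0))
}

#' Intravascular retention fraction of infused crystalloid
#'
#' Retention is `crystalloid_retention_max` at or below the lower pressure
#' knee, `crystalloid_retention_min` at or above the upper knee, and linear in
#' between: higher pressures redistribute more fluid to the interstitium.
#'
#' @param params a `subject_params` object.
#' @param map current MAP in mmHg (>= 0).
#' @return retention fraction in \[0, 1\].
#' @export
crystalloid_retention <- function(params, map) {
  stopifnot(all(map >= 0))
  lo <- params$retention_knee_low
  hi <- params$retention_knee_high
  frac <- pmin(1, pmax(0, (map - lo) / (hi - lo)))
  params$crystalloid_retention_max -
    frac * (params$crystalloid_retention_max - params$crystalloid_retention_min)
}

#' Signed fluid-transfer order for the pump
#'
#' @param rate mL/min; positive infuses into the subject, negative withdraws.
#' @param fluid `"whole_blood"` or `"crystalloid"`; withdrawal is only allowed
#'   as whole blood.
#' @param source_hct hematocrit of infused whole blood (e.g. the blood bag's);
#'   ignored for crystalloid and withdrawal.
#' @return a `pump_command` object.
#' @export
pump_command <- function(rate = 0, fluid = c("whole_blood", "crystalloid"),
                         source_hct = NA_real_) {
  fluid <- match.arg(fluid)
  stopifnot(is.numeric(rate), length(rate) == 1, is.finite(rate))
  if (rate < 0 && fluid != "whole_blood") {
    stop("withdrawal is only permitted as whole blood", call. = FALSE)
  }
  if (rate > 0 && fluid == "whole_blood" && !is.finite(source_hct)) {
    stop("whole-blood infusion requires a finite source_hct", call. = FALSE)
  }
  structure(list(rate = rate, fluid = fluid, source_hct = source_hct),
            class = "pump_command")
}

#' Advance the subject state by one time step
#'
#' Applies a pump command for `dt` minutes: whole blood adds (or removes)
#' volume and red cells; crystalloid splits between the intravascular and
#' interstitial compartments according to the pressure-dependent retention
#' fraction; retained crystalloid leaks to the interstitium in proportion to
#' the pressure excess above the lower retention knee; MAP, CVP, lactate and
#' hematocrit are then recomputed. Lactate rises at the anesthetic-stratified
#' rate while MAP is below the ischemia threshold and falls at the
#' infusate-specific clearance rate once MAP has been at or above the
#' clearance threshold continuously for `clearance_lag` minutes, floored at
#' the baseline level.
#'
#' @param params a `subject_params` object.
#' @param state a `subject_state` object.
#' @param command a `pump_command` object.
#' @param dt step length in minutes (1/60, i.e. one second, recommended).
#' @param pump_max maximum pump rate magnitude in mL/min; faster commands are
#'   rejected.
#' @return the updated `subject_state`.
#' @export
step_subject <- function(params, state, command, dt = 1 / 60, pump_max = 600) {
  stopifnot(dt > 0)
  if (!state$alive) stop("subject is not alive", call. = FALSE)
  if (abs(command$rate) > pump_max) {
    stop("pump command exceeds maximum rate (", pump_max, " mL/min)", call. = FALSE)
  }

  v <- state$intravascular_volume
  rbc <- state$rbc_volume
  cry <- state$crystalloid_volume
  inter <- state$interstitial_excess
  map0 <- state$map
  vol <- command$rate * dt

  if (vol > 0) {
    if (command$fluid == "whole_blood") {
      v <- v + vol
      rbc <- rbc + vol * command$source_hct
      state$cum_wb_infused <- state$cum_wb_infused + vol
    } else {
      ret <- crystalloid_retention(params, map0)
      v <- v + ret * vol
      cry <- cry + ret * vol
      inter <- inter + (1 - ret) * vol
      state$cum_crystalloid_retained <- state$cum_crystalloid_retained + ret * vol
    }
  } else if (vol < 0) {
    w <- -vol
    hct_now <- rbc / v
    rbc <- rbc - w * hct_now
    cry <- cry - w * (cry / v)
    v <- v - w
    state$cum_withdrawn <- state$cum_withdrawn + w
  }

  # pressure-driven leak of retained crystalloid to the interstitium
  leak <- params$leak_rate * max(0, map0 - params$retention_knee_low) * cry * dt
  leak <- min(leak, cry)
  cry <- cry - leak
  v <- v - leak
  inter <- inter + leak
  state$cum_leaked <- state$cum_leaked + leak

  if (v <= 0) {
    state$alive <- FALSE
    state$intravascular_volume <- .Machine$double.eps
    state$map <- 0
    state$time <- state$time + dt
    return(state)
  }

  v0 <- reference_volume(params)
  map <- max(0, params$baseline_map + params$wb_slope * (v - v0))
  cvp <- params$baseline_cvp + params$cvp_volume_gain * (v - v0) +
    params$cvp_interstitial_gain * inter

  lac <- state$lactate
  tac <- state$time_above_clearance_threshold
  if (map < params$ischemia_map_threshold) {
    lac <- lac + params$lactate_accum_rate / 60 * dt
    tac <- 0
  } else if (map >= params$clearance_map_threshold) {
    tac <- tac + dt
    if (tac >= params$clearance_lag) {
      cr <- if (command$fluid == "crystalloid") params$lactate_clear_rate_crystalloid
            else params$lactate_clear_rate_wb
      lac <- max(params$baseline_lactate, lac - cr / 60 * dt)
    }
  } else {
    tac <- 0
  }

  state$time <- state$time + dt
  state$intravascular_volume <- v
  state$interstitial_excess <- inter
  state$crystalloid_volume <- cry
  state$rbc_volume <- rbc
  state$map <- map
  state$cvp <- cvp
  state$lactate <- lac
  state$hct <- rbc / v
  state$time_above_clearance_threshold <- tac
  state
}

#' Noisy vitals sample from the current state
#'
#' Adds Gaussian noise of standard deviation `noise_sd` to the pressure
#' channels; the underlying state is untouched. Lactate is only reported when
#' a scheduled draw is due (`lactate_due = TRUE`), emulating the 10-minute
#' point-of-care sampling cadence.
#'
#' @param state a `subject_state`.
#' @param params a `subject_params`.
#' @param lactate_due whether a lactate draw is scheduled at this instant.
#' @return a list with `map`, `cvp` and (possibly `NA`) `lactate`.
#' @export
sample_vitals <- function(state, params, lactate_due = FALSE) {
  sd <- params$noise_sd
  list(
    map = state$map + if (sd > 0) stats::rnorm(1, 0, sd) else 0,
    cvp = state$cvp + if (sd > 0) stats::rnorm(1, 0, sd) else 0,
    lactate = if (lactate_due) state$lactate else NA_real_
  )
}
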