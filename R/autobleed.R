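# Decision-table hemorrhage controller: drives the subject to a hypotensive
# target, holds it by withdrawing/reinfusing blood, co-infuses anticoagulant
# at a fixed volumetric ratio, and tracks the blood bag.

#' Default AutoBleed decision table
#'
#' Magnitude bands on the absolute MAP error `|map - target|` (mmHg) mapped to
#' unsigned rates (mL/min); the commanded rate opposes the error sign
#' (above target withdraws, below target reinfuses). The innermost band is the
#' hold tolerance where the rate is zero.
#'
#' @return a tibble with columns `error_above` (band lower edge, exclusive for
#'   the first band above the tolerance, inclusive beyond) and
#'   `rate_magnitude`.
#' @export
default_decision_table <- function() {
  tibble::tibble(
    error_above = c(0, 2, 4, 10),
    rate_magnitude = c(0, 10, 25, 60)
  )
}

#' AutoBleed configuration
#'
#' @param target_map hypotensive hold target, mmHg.
#' @param tolerance hold tolerance band, mmHg; the rate is zero when holding
#'   within `target_map +/- tolerance`.
#' @param decision_table tibble of magnitude bands, see
#'   [default_decision_table()].
#' @param cpda_ratio blood:anticoagulant volumetric mixing ratio (7 means 1
#'   part CPDA-1 per 7 parts withdrawn blood).
#' @param filter_window seconds of raw samples pooled by the pressure filter.
#' @param control_interval seconds between rate updates.
#' @param creep_rate unsigned rate (mL/min) used to finish the approach to the
#'   target once inside the tolerance band (hysteresis: the controller keeps
#'   moving until the error crosses zero, then idles).
#' @return an `autobleed_config` object.
#' @export
autobleed_config <- function(target_map = 35, tolerance = 2,
                             decision_table = default_decision_table(),
                             cpda_ratio = 7, filter_window = 10,
                             control_interval = 10, creep_rate = 10) {
  stopifnot(
    "tolerance must be > 0" = tolerance > 0,
    "cpda_ratio must be > 0" = cpda_ratio > 0,
    "decision table must have increasing bands" =
      !is.unsorted(decision_table$error_above, strictly = TRUE),
    "decision table rates must be non-decreasing in the error" =
      !is.unsorted(decision_table$rate_magnitude),
    "innermost decision band must be the zero band" =
      decision_table$rate_magnitude[1] == 0
  )
  structure(list(
    target_map = target_map, tolerance = tolerance,
    decision_table = decision_table, cpda_ratio = cpda_ratio,
    filter_window = filter_window, control_interval = control_interval,
    creep_rate = creep_rate
  ), class = "autobleed_config")
}

#' Fresh AutoBleed controller state
#' @param config an `autobleed_config`.
#' @return an `autobleed_state` object.
#' @export
new_autobleed_state <- function(config = autobleed_config()) {
  structure(list(mode = "idle"), class = "autobleed_state")
}

#' Decision-table lookup: signed rate from filtered MAP
#'
#' Stateless rule: zero inside the tolerance band, otherwise the table rate
#' for the error magnitude, signed to oppose the error (negative = withdraw).
#'
#' @param filtered_map filtered MAP, mmHg.
#' @param config an `autobleed_config`.
#' @return signed rate, mL/min.
#' @export
decision_rate <- function(filtered_map, config = autobleed_config()) {
  e <- filtered_map - config$target_map
  if (abs(e) <= config$tolerance) return(0)
  tbl <- config$decision_table
  band <- max(which(abs(e) >= tbl$error_above))
  # the first band above the tolerance opens at its lower edge (exclusive)
  mag <- tbl$rate_magnitude[band]
  -sign(e) * mag
}

#' Anticoagulant co-infusion rate
#'
#' CPDA-1 is mixed with withdrawn blood at a fixed volumetric ratio
#' (1 part anticoagulant per `cpda_ratio` parts blood); none flows during
#' reinfusion.
#'
#' @param blood_withdrawal_rate unsigned withdrawal rate, mL/min.
#' @param cpda_ratio blood:anticoagulant ratio.
#' @return anticoagulant rate, mL/min.
#' @export
cpda_rate <- function(blood_withdrawal_rate, cpda_ratio = 7) {
  if (any(blood_withdrawal_rate < 0)) {
    stop("withdrawal rate magnitude must be non-negative", call. = FALSE)
  }
  blood_withdrawal_rate / cpda_ratio
}

#' An empty blood bag
#' @return a `blood_bag` object.
#' @export
new_blood_bag <- function() {
  structure(list(blood_volume = 0, cpda_volume = 0, rbc_volume = 0, hct = 0,
                 temperature_held = TRUE),
            class = "blood_bag")
}

#' Total mixed volume in the bag, mL
#' @param bag a `blood_bag`.
#' @export
bag_volume <- function(bag) bag$blood_volume + bag$cpda_volume

#' Update the blood bag for withdrawn blood, anticoagulant, and reinfusion
#'
#' Withdrawn blood carries red cells at the subject's current hematocrit;
#' the bag hematocrit is the red-cell mass balance over the total mixed
#' volume. Reinfusion draws proportionally from the mixed contents (blood,
#' anticoagulant and red cells alike), so the bag hematocrit is unchanged by
#' reinfusion.
#'
#' @param bag a `blood_bag`.
#' @param withdrawn_ml blood volume added to the bag, mL (>= 0).
#' @param subject_hct hematocrit of the withdrawn blood.
#' @param cpda_ml anticoagulant volume added, mL (>= 0).
#' @param reinfused_ml mixed volume drawn back out, mL (>= 0); requesting more
#'   than the bag holds is an error.
#' @return the updated `blood_bag`.
#' @export
bag_update <- function(bag, withdrawn_ml = 0, subject_hct = 0, cpda_ml = 0,
                       reinfused_ml = 0) {
  stopifnot(withdrawn_ml >= 0, cpda_ml >= 0, reinfused_ml >= 0)
  bag$blood_volume <- bag$blood_volume + withdrawn_ml
  bag$cpda_volume <- bag$cpda_volume + cpda_ml
  bag$rbc_volume <- bag$rbc_volume + withdrawn_ml * subject_hct
  total <- bag$blood_volume + bag$cpda_volume
  if (reinfused_ml > 0) {
    if (reinfused_ml > total + 1e-9) {
      stop("reinfusion request exceeds bag volume", call. = FALSE)
    }
    f <- min(1, reinfused_ml / total)
    bag$blood_volume <- bag$blood_volume * (1 - f)
    bag$cpda_volume <- bag$cpda_volume * (1 - f)
    bag$rbc_volume <- bag$rbc_volume * (1 - f)
    total <- bag$blood_volume + bag$cpda_volume
  }
  bag$hct <- if (total > 0) bag$rbc_volume / total else 0
  bag
}

#' One control tick of AutoBleed
#'
#' Filters the raw MAP samples, looks up the signed rate in the decision
#' table, and applies approach hysteresis: once moving toward the target the
#' controller keeps a creep rate inside the tolerance band until the error
#' crosses zero, then idles until MAP leaves the band again. Returns the
#' subject pump command and the anticoagulant co-infusion rate; the bag is
#' passed through untouched (volume accounting happens as fluid actually
#' moves, via [bag_update()] in the simulation loop).
#'
#' @param ab_state an `autobleed_state`.
#' @param map_samples raw MAP samples since the previous tick, mmHg.
#' @param config an `autobleed_config`.
#' @param bag the current `blood_bag` (supplies the reinfusion hematocrit).
#' @param engaged whether AutoBleed is engaged this phase; when `FALSE` the
#'   command is zero.
#' @return a list with `command` (a `pump_command`), `cpda_rate_ml_min`,
#'   `state`, `bag` and `filtered_map`.
#' @export
autobleed_step <- function(ab_state, map_samples, config = autobleed_config(),
                           bag = new_blood_bag(), engaged = TRUE) {
  fmap <- filter_pressure(map_samples)
  if (!engaged) {
    return(list(command = pump_command(0, "whole_blood"),
                cpda_rate_ml_min = 0, state = ab_state, bag = bag,
                filtered_map = fmap))
  }
  e <- fmap - config$target_map
  rate <- decision_rate(fmap, config)
  if (rate == 0) {
    # inside the tolerance band: finish the approach, then idle
    if (ab_state$mode == "withdrawing" && e > 0) {
      rate <- -config$creep_rate
    } else if (ab_state$mode == "reinfusing" && e < 0) {
      rate <- config$creep_rate
    } else {
      ab_state$mode <- "idle"
    }
  }
  if (rate < 0) ab_state$mode <- "withdrawing"
  if (rate > 0) ab_state$mode <- "reinfusing"
  if (rate > 0 && bag_volume(bag) <= 0) rate <- 0  # nothing left to reinfuse

  cmd <- pump_command(rate, "whole_blood",
                      source_hct = if (rate > 0) bag$hct else NA_real_)
  list(command = cmd,
       cpda_rate_ml_min = if (rate < 0) cpda_rate(-rate, config$cpda_ratio) else 0,
       state = ab_state, bag = bag, filtered_map = fmap)
}
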