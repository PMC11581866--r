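# Synthetic subject model: parameters, pressure-volume law, crystalloid
# kinetics, lactate dynamics, hematocrit, and conservation bookkeeping.

quiet <- list(noise_sd = 0)

test_that("defaults give a 40 kg subject with 2800 mL reference volume", {
  p <- make_subject()
  expect_equal(reference_volume(p), 2800)
  expect_equal(p$baseline_map, 65)
  expect_equal(p$wb_slope, 0.03)
  expect_equal(p$baseline_hct, 0.30)
})

test_that("anesthetic strata set the lactate accumulation rate", {
  expect_equal(make_subject()$lactate_accum_rate, 4.95)
  expect_equal(make_subject(list(anesthetic = "isoflurane"))$lactate_accum_rate, 2.49)
  expect_equal(make_subject(list(anesthetic = "propofol"))$lactate_accum_rate, 3.61)
  expect_error(make_subject(list(anesthetic = "sevoflurane")), "unknown anesthetic")
  # an explicit override wins over the stratum mapping
  expect_equal(make_subject(list(lactate_accum_rate = 1.5))$lactate_accum_rate, 1.5)
})

test_that("make_subject rejects unknown or malformed overrides", {
  expect_error(make_subject(list(bogus = 1)), "unknown subject parameter")
  expect_error(make_subject(list(40)), "named list")
  expect_error(make_subject(list(wb_slope = -0.01)))
  expect_error(make_subject(list(baseline_hct = 1.2)))
  expect_error(make_subject(list(noise_sd = -1)))
  expect_error(make_subject(list(weight = NA_real_)), "non-finite")
})

test_that("jitter requires a seed, is reproducible, and preserves the RNG", {
  expect_error(make_subject(jitter = 0.1), "seed")
  a <- make_subject(seed = 7, jitter = 0.1)
  b <- make_subject(seed = 7, jitter = 0.1)
  expect_identical(a, b)
  c <- make_subject(seed = 8, jitter = 0.1)
  expect_false(identical(a$wb_slope, c$wb_slope))
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(make_subject(seed = 7, jitter = 0.1))
  expect_identical(rnorm(1), before)
})

test_that("MAP follows the linear pressure-volume law", {
  p <- make_subject(quiet)
  expect_equal(map_from_volume(p, 2800), 65)
  expect_equal(map_from_volume(p, 1800), 35)   # a 1000 mL bleed spans 65 -> 35
  expect_equal(map_from_volume(p, 2900), 68)
  expect_equal(map_from_volume(p, 10), 0)      # floored at 0
  expect_error(map_from_volume(p, 0), "positive")
  expect_error(map_from_volume(p, -5), "positive")
})

test_that("crystalloid retention is the documented piecewise-linear curve", {
  p <- make_subject(quiet)
  expect_equal(crystalloid_retention(p, 0), 0.80)
  expect_equal(crystalloid_retention(p, 45), 0.80)
  expect_equal(crystalloid_retention(p, 65), 0.25)
  expect_equal(crystalloid_retention(p, 100), 0.25)
  expect_equal(crystalloid_retention(p, 55), (0.80 + 0.25) / 2)
  # linearity between the knees
  expect_equal(crystalloid_retention(p, 50), 0.80 - 0.25 * (0.80 - 0.25))
})

test_that("pump_command validates fluid/rate combinations", {
  expect_error(pump_command(-10, "crystalloid"), "whole blood")
  expect_error(pump_command(10, "whole_blood"), "source_hct")
  expect_silent(pump_command(10, "whole_blood", source_hct = 0.3))
  expect_silent(pump_command(-10, "whole_blood"))
  expect_silent(pump_command(10, "crystalloid"))
  expect_error(pump_command(Inf, "crystalloid"))
})

test_that("step_subject enforces the pump limit and refuses dead subjects", {
  p <- make_subject(quiet)
  s <- new_subject_state(p)
  expect_error(step_subject(p, s, pump_command(-700, "whole_blood")), "maximum rate")
  s2 <- step_subject(p, s, pump_command(-600, "whole_blood"), dt = 10)
  expect_false(s2$alive)
  expect_equal(s2$map, 0)
  expect_error(step_subject(p, s2, pump_command(0, "whole_blood")), "not alive")
})

test_that("whole-blood infusion moves volume, red cells and MAP linearly", {
  p <- make_subject(quiet)
  s <- new_subject_state(p)
  s <- step_subject(p, s, pump_command(60, "whole_blood", source_hct = 0.25), dt = 1)
  expect_equal(s$intravascular_volume, 2860)
  expect_equal(s$rbc_volume, 2800 * 0.3 + 60 * 0.25)
  expect_equal(s$map, 65 + 0.03 * 60)
  expect_equal(s$cum_wb_infused, 60)
})

test_that("withdrawal removes blood at the current hematocrit", {
  p <- make_subject(quiet)
  s <- new_subject_state(p)
  s <- step_subject(p, s, pump_command(-60, "whole_blood"), dt = 1)
  expect_equal(s$intravascular_volume, 2740)
  expect_equal(s$cum_withdrawn, 60)
  # proportional removal leaves the hematocrit unchanged
  expect_equal(s$hct, 0.30)
  expect_equal(s$map, 65 - 0.03 * 60)
})

test_that("crystalloid splits by the retention fraction and dilutes hct", {
  p <- make_subject(c(quiet, list(leak_rate = 0)))
  s <- new_subject_state(p)
  # at baseline MAP 65 the retention fraction is 0.25
  s <- step_subject(p, s, pump_command(100, "crystalloid"), dt = 1)
  expect_equal(s$intravascular_volume, 2800 + 25)
  expect_equal(s$crystalloid_volume, 25)
  expect_equal(s$interstitial_excess, 75)
  expect_equal(s$cum_crystalloid_retained, 25)
  expect_lt(s$hct, 0.30)
  expect_equal(s$hct, s$rbc_volume / s$intravascular_volume)
})

test_that("retained crystalloid leaks at the configured pressure-scaled rate", {
  p <- make_subject(quiet)
  s <- new_subject_state(p)
  s$crystalloid_volume <- 100
  s <- step_subject(p, s, pump_command(0, "whole_blood"), dt = 1)
  # leak = 0.004 * (65 - 45) * 100 * 1 = 8 mL
  expect_equal(s$cum_leaked, 8)
  expect_equal(s$crystalloid_volume, 92)
  expect_equal(s$interstitial_excess, 8)
  # no leak at or below the lower knee
  p2 <- make_subject(c(quiet, list(baseline_map = 45)))
  s2 <- new_subject_state(p2)
  s2$crystalloid_volume <- 100
  s2 <- step_subject(p2, s2, pump_command(0, "whole_blood"), dt = 1)
  expect_equal(s2$cum_leaked, 0)
})

test_that("CVP responds to intravascular deficit and interstitial excess", {
  p <- make_subject(quiet)
  s <- new_subject_state(p)
  expect_equal(s$cvp, 5)
  s1 <- step_subject(p, s, pump_command(-60, "whole_blood"), dt = 1)
  expect_equal(s1$cvp, 5 + 0.004 * (s1$intravascular_volume - 2800))
  s2 <- new_subject_state(p)
  s2$interstitial_excess <- 500
  s2 <- step_subject(p, s2, pump_command(0, "whole_blood"), dt = 1 / 60)
  expect_equal(s2$cvp, 5 + 0.002 * 500)
})

test_that("lactate accumulates below the ischemia threshold at the stratum rate", {
  p <- make_subject(c(quiet, list(baseline_map = 30)))
  s <- new_subject_state(p)
  dt <- 1 / 60
  for (i in 1:60) s <- step_subject(p, s, pump_command(0, "whole_blood"), dt)
  expect_equal(s$lactate, 1.0 + 4.95 / 60, tolerance = 1e-9)
  expect_equal(s$time_above_clearance_threshold, 0)
})

test_that("lactate clears only after the continuous-lag clock elapses", {
  p <- make_subject(c(quiet, list(baseline_map = 60)))
  dt <- 1 / 60
  s <- new_subject_state(p)
  s$lactate <- 5
  for (i in 1:1500) s <- step_subject(p, s, pump_command(0, "whole_blood"), dt)
  # clearing (1.0 mmol/L/hr on whole blood) starts once the clock hits 20 min,
  # i.e. for steps 1200..1500 of the 25-minute run
  expect_equal(s$lactate, 5 - 301 * (1.0 / 60) * dt, tolerance = 1e-8)

  # crystalloid clears twice as fast
  s2 <- new_subject_state(p)
  s2$lactate <- 5
  for (i in 1:1500) s2 <- step_subject(p, s2, pump_command(0.001, "crystalloid"), dt)
  expect_lt(s2$lactate, s$lactate)

  # MAP dipping between the thresholds resets the clock and freezes lactate
  s3 <- new_subject_state(p)
  s3$lactate <- 5
  s3$time_above_clearance_threshold <- 19.9
  s3 <- step_subject(p, s3, pump_command(-600, "whole_blood"), dt = 0.5)  # MAP ~51
  expect_equal(s3$time_above_clearance_threshold, 0)
  expect_equal(s3$lactate, 5)
})

test_that("lactate is floored at the baseline level", {
  p <- make_subject(c(quiet, list(baseline_map = 60, clearance_lag = 0)))
  dt <- 1 / 60
  s <- new_subject_state(p)
  s$lactate <- 1.005
  for (i in 1:120) s <- step_subject(p, s, pump_command(0, "whole_blood"), dt)
  expect_equal(s$lactate, 1.0)
})

test_that("fluid bookkeeping stays conservative over a mixed random run", {
  p <- make_subject(quiet)
  s <- new_subject_state(p)
  set.seed(42)
  dt <- 1 / 60
  for (i in 1:600) {
    r <- runif(1, -100, 200)
    cmd <- if (r < 0) pump_command(r, "whole_blood") else
      if (runif(1) < 0.5) pump_command(r, "crystalloid") else
        pump_command(r, "whole_blood", source_hct = 0.28)
    s <- step_subject(p, s, cmd, dt)
  }
  expect_true(s$alive)
  expect_lt(conservation_gap(s, p), 1e-6)
})

test_that("sample_vitals is exact at noise 0 and gates lactate on the draw flag", {
  p <- make_subject(quiet)
  s <- new_subject_state(p)
  v <- sample_vitals(s, p)
  expect_equal(v$map, s$map)
  expect_equal(v$cvp, s$cvp)
  expect_true(is.na(v$lactate))
  expect_equal(sample_vitals(s, p, lactate_due = TRUE)$lactate, s$lactate)
  pn <- make_subject()
  set.seed(1)
  vn <- sample_vitals(s, pn)
  expect_false(vn$map == s$map)
})
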