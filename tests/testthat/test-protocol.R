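# Protocol orchestration: shock criterion, session runners, the two-event
# timeline, cohort aggregation, and the tidier methods.

quiet <- list(noise_sd = 0)

test_that("shock criterion fires on lactate first, then on timeout", {
  r <- tibble::tibble(time_min = c(10, 20, 30), lactate = c(2, 3.5, 4.2))
  hit <- shock_criterion(r, threshold = 4, max_duration = 90, hold_start = 10)
  expect_true(hit$met)
  expect_equal(hit$reason, "lactate")
  expect_equal(hit$time, 30)

  slow <- tibble::tibble(time_min = seq(10, 100, 10), lactate = seq(1, 1.9, 0.1))
  out <- shock_criterion(slow, 4, max_duration = 90, hold_start = 10)
  expect_true(out$met)
  expect_equal(out$reason, "timeout")
  expect_equal(out$time, 100)

  open <- shock_criterion(slow[1:3, ], 4, 90, hold_start = 10)
  expect_false(open$met)
  expect_true(is.na(open$time))
})

test_that("lactate_slope is the least-squares slope in mmol/L/hr", {
  r <- tibble::tibble(time_min = c(0, 10, 20, 30), lactate = c(1, 1.5, 2, 2.5))
  expect_equal(lactate_slope(r), 3)  # 0.05 mmol/L/min
  expect_true(is.na(lactate_slope(r[1, ])))
  # matches the normal-equations oracle on noisy readings
  set.seed(3)
  rn <- tibble::tibble(time_min = seq(0, 60, 10),
                       lactate = 1 + 0.04 * seq(0, 60, 10) + rnorm(7, 0, 0.1))
  expect_equal(lactate_slope(rn),
               oracle_ols_slope(rn$time_min, rn$lactate) * 60,
               tolerance = 1e-9)
})

test_that("an AutoBleed session reaches and holds the hypotensive band", {
  p <- make_subject(quiet)
  out <- run_autobleed_session(p, duration = 45, seed = 1)
  tr <- out$trace
  expect_true(all(diff(tr$time_min) > 0))
  # reaches the band and stays there
  late <- tr$map_mmHg[tr$time_min >= 30]
  expect_true(all(abs(late - 35) <= 2))
  # withdrawal-only net flow: blood accumulates in the bag, with 1:7 CPDA
  expect_gt(out$bag$blood_volume, 800)
  expect_equal(out$bag$cpda_volume * 7, out$bag$blood_volume, tolerance = 1e-9)
  # decision log records the co-infusion pairing exactly
  d <- out$decisions
  w <- d$commanded_rate_mL_min < 0
  expect_equal(d$cpda_rate_mL_min[w], -d$commanded_rate_mL_min[w] / 7)
  expect_true(all(d$cpda_rate_mL_min[!w] == 0))
})

test_that("an ARC session rises, stabilizes, and enters maintenance", {
  p <- make_subject(quiet)
  st <- new_subject_state(p)
  st$intravascular_volume <- 1800
  st$rbc_volume <- 1800 * 0.3
  st$map <- map_from_volume(p, 1800)
  out <- run_arc_session(p, st, duration = 40, stop_fn = function(cx) {
    if (cx$controller$arc_state$phase == "maintenance") "done" else NULL
  })
  expect_equal(out$stop_reason, "done")
  expect_false(is.na(out$arc_state$attained_time))
  ph <- unique(out$trace$phase)
  expect_equal(ph, c("resuscitation1", "stabilization1", "maintenance1"))
  # ARC never withdraws
  expect_true(all(out$trace$infusion_mL_min >= 0))
  # within the rise, MAP is non-decreasing on the noise-free linear subject
  rise <- out$trace$map_mmHg[out$trace$phase == "resuscitation1"]
  expect_true(all(diff(rise) >= -1e-9))
})

# One noise-free run through the first event, shared by the tests below.
res1 <- run_protocol(make_subject(quiet), seed = 1, stop_after = "event1")

test_that("protocol phases appear once each, in order, with contiguous time", {
  ph <- rle(res1$trace$phase)$values
  expect_equal(ph, c("baseline", "hemorrhage1", "hold1", "resuscitation1",
                     "stabilization1", "maintenance1"))
  expect_true(all(diff(res1$trace$time_min) > 0))
  expect_equal(max(res1$trace$time_min),
               nrow(res1$trace) * res1$protocol$dt, tolerance = 1e-6)
})

test_that("the first hold ends on the lactate criterion with 10-min readings", {
  expect_equal(res1$holds$first_reason, "lactate")
  h1 <- res1$lactate_readings[res1$lactate_readings$phase == "hold1", ]
  expect_true(all(abs(diff(h1$time_min) - 10) < 1e-6))
  expect_gte(max(h1$lactate), 4)
  expect_true(all(h1$lactate[-nrow(h1)] < 4))  # it ends at the first crossing
})

test_that("event 1 resuscitates on whole blood and maintains on crystalloid", {
  tr <- res1$trace
  expect_true(all(tr$fluid[tr$phase == "resuscitation1" & tr$infusion_mL_min > 0]
                  == "whole_blood"))
  expect_true(all(tr$fluid[tr$phase == "maintenance1" & tr$infusion_mL_min > 0]
                  == "crystalloid"))
  expect_true(res1$flags$target_reached_1)
  expect_equal(nrow(res1$metrics), 1)
  expect_true(all(is.finite(as.numeric(
    res1$metrics[1, arcsim:::metric_order]))))
})

test_that("trace infusion integrals match the subject's bookkeeping counters", {
  tr <- res1$trace
  dt <- res1$protocol$dt
  st <- res1$final_state
  wb <- sum(tr$infusion_mL_min[tr$fluid == "whole_blood" & tr$infusion_mL_min > 0]) * dt
  wd <- -sum(tr$infusion_mL_min[tr$infusion_mL_min < 0]) * dt
  expect_equal(wb, st$cum_wb_infused, tolerance = 1e-6)
  expect_equal(wd, st$cum_withdrawn, tolerance = 1e-6)
  expect_lt(conservation_gap(st, res1$params), 1e-6)
  # interstitial fluid = unretained crystalloid + leaked retained crystalloid
  cry <- sum(tr$infusion_mL_min[tr$fluid == "crystalloid" & tr$infusion_mL_min > 0]) * dt
  expect_equal(st$interstitial_excess,
               (cry - st$cum_crystalloid_retained) + st$cum_leaked,
               tolerance = 1e-6)
})

test_that("volumes, events and glance summarize the run consistently", {
  v <- res1$volumes
  # the noise-free whole-blood event needs no maintenance crystalloid: MAP
  # holds itself, so only the resuscitation infusate appears
  expect_true("whole_blood" %in% v$fluid)
  expect_true(all(v$volume_mL > 0))
  expect_equal(sum(v$volume_mL),
               sum(res1$trace$infusion_mL_min[res1$trace$infusion_mL_min > 0 &
                     res1$trace$phase %in% c("resuscitation1", "stabilization1",
                                             "maintenance1")]) * res1$protocol$dt,
               tolerance = 1e-6)
  ev <- res1$events
  expect_lt(ev$time_min[ev$event == "hold1_start"],
            ev$time_min[ev$event == "resuscitation1_start"])
  g <- glance(res1)
  expect_equal(nrow(g), 1)
  expect_true(g$target_reached_1)
  expect_equal(g$hold1_min, res1$holds$first)
  td <- tidy(res1)
  expect_equal(nrow(td), 12)
  expect_setequal(td$metric, arcsim:::metric_order)
})

test_that("stopping after hold1 skips resuscitation entirely", {
  r <- run_protocol(make_subject(quiet), seed = 2, stop_after = "hold1")
  expect_null(r$metrics)
  expect_equal(rle(r$trace$phase)$values, c("baseline", "hemorrhage1", "hold1"))
  expect_true(is.na(r$holds$second_planned))
})

test_that("identical seeds reproduce a noisy run exactly", {
  p <- make_subject()  # default noise_sd = 2
  a <- run_protocol(p, seed = 11, stop_after = "hold1")
  b <- run_protocol(p, seed = 11, stop_after = "hold1")
  expect_identical(a$trace, b$trace)
  expect_identical(a$lactate_readings, b$lactate_readings)
  c <- run_protocol(p, seed = 12, stop_after = "hold1")
  expect_false(identical(a$trace$map_raw_mmHg, c$trace$map_raw_mmHg))
})

test_that("run_cohort strata, per-subject slopes, and tidiers line up", {
  expect_error(run_cohort(3, ketamine = 1, isoflurane = 1), "sum to n")
  co <- run_cohort(2, ketamine = 1, isoflurane = 1, base_seed = 5,
                   overrides = quiet, stop_after = "hold1")
  expect_equal(nrow(co$subjects), 2)
  expect_equal(co$subjects$anesthetic, c("ketamine", "isoflurane"))
  expect_equal(co$subjects$seed, c(6, 7))
  # noise-free linear accumulation: the OLS slope is the stratum rate
  expect_equal(co$subjects$lactate_slope_mmol_L_hr, c(4.95, 2.49),
               tolerance = 1e-6)
  lac <- co$summary$lactate
  expect_equal(lac$mean_slope[lac$anesthetic == "pooled"], mean(c(4.95, 2.49)),
               tolerance = 1e-6)
  expect_identical(tidy(co), co$subjects)
  g <- glance(co)
  expect_equal(g$n, 2)
  expect_equal(g$lactate_slope_mean, lac$mean_slope[lac$anesthetic == "pooled"])
})

test_that("cohort runs are independent of stratum ordering in aggregate", {
  a <- run_cohort(2, ketamine = 1, isoflurane = 1, base_seed = 21,
                  overrides = quiet, stop_after = "hold1")
  # same subjects under the same seeds give the same pooled statistics
  b <- run_cohort(2, ketamine = 1, isoflurane = 1, base_seed = 21,
                  overrides = quiet, stop_after = "hold1")
  expect_equal(a$summary$lactate, b$summary$lactate)
})

test_that("autoplot and plot_trace return ggplot objects", {
  expect_s3_class(autoplot(res1), "ggplot")
  expect_s3_class(plot_trace(res1$trace), "ggplot")
  co <- run_cohort(2, ketamine = 1, isoflurane = 1, base_seed = 5,
                   overrides = quiet, stop_after = "hold1")
  expect_s3_class(autoplot(co), "ggplot")
})
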