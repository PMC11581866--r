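# Independent, deliberately naive reference implementations used to check the
# package's vectorised metric code. Everything here is written from the metric
# definitions with explicit loops / normal equations, sharing no code with R/.

oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

oracle_sd <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

oracle_trapz <- function(t, y) {
  s <- 0
  for (i in seq_len(length(t) - 1)) {
    s <- s + (t[i + 1] - t[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

# Simple-regression slope via the normal equations, solved directly.
oracle_ols_slope <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  unname(beta[2, 1])
}

# All twelve event metrics, computed longhand from their definitions.
oracle_event_metrics <- function(trace, start = NULL, band = 5) {
  if (is.null(start)) start <- trace$time_min[1]
  n <- nrow(trace)
  pe <- numeric(n)
  dev <- numeric(n)
  for (i in seq_len(n)) {
    dev[i] <- trace$map_mmHg[i] - trace$target_mmHg[i]
    pe[i] <- 100 * dev[i] / trace$target_mmHg[i]
  }
  mdpe <- oracle_median(pe)
  mdape <- oracle_median(abs(pe))
  wobble <- oracle_median(abs(pe - mdpe))

  in_band <- 0
  not_under <- 0
  for (i in seq_len(n)) {
    if (abs(dev[i]) <= band) in_band <- in_band + 1
    if (dev[i] >= -band) not_under <- not_under + 1
  }

  rise <- NA_real_
  for (i in seq_len(n)) {
    if (trace$time_min[i] >= start && trace$map_mmHg[i] >= trace$target_mmHg[i]) {
      rise <- trace$time_min[i] - start
      break
    }
  }
  over <- 0
  for (i in seq_len(n)) over <- max(over, dev[i] / trace$target_mmHg[i])
  over <- max(0, over)

  list(
    mdpe = mdpe, mdape = mdape, wobble = wobble,
    effectiveness = 100 * in_band / n,
    resuscitation_effectiveness = 100 * not_under / n,
    target_overshoot = 100 * over,
    area_above = oracle_trapz(trace$time_min, pmax(dev, 0)),
    area_below = -oracle_trapz(trace$time_min, pmax(-dev, 0)),
    rise_time = rise,
    median_infusion = oracle_median(trace$infusion_mL_min),
    mean_infusion = sum(trace$infusion_mL_min) / n,
    infusion_variability = oracle_sd(trace$infusion_mL_min)
  )
}

metric_names <- c(
  "mdpe", "mdape", "wobble", "effectiveness", "resuscitation_effectiveness",
  "target_overshoot", "area_above", "area_below", "rise_time",
  "median_infusion", "mean_infusion", "infusion_variability"
)

# Random event-shaped trace: uniform time grid, positive (possibly stepped)
# target, noisy oscillating MAP, non-negative infusion rates.
random_trace <- function(n, seed) {
  set.seed(seed)
  dt <- stats::runif(1, 0.005, 0.05)
  t0 <- stats::runif(1, 0, 100)
  time <- t0 + (0:(n - 1)) * dt
  base_target <- stats::runif(1, 40, 80)
  tgt <- rep(base_target, n)
  if (stats::runif(1) < 0.5) {
    drops <- cumsum(sample(c(0, 0, 0, 0.2), n, replace = TRUE))
    tgt <- pmax(30, base_target - drops)
  }
  map <- tgt + stats::rnorm(n, 0, 6) + 8 * sin(time / 2)
  inf <- pmax(0, stats::rnorm(n, 8, 12))
  tibble::tibble(time_min = time, map_mmHg = map, target_mmHg = tgt,
                 infusion_mL_min = inf)
}

# |a - b| <= tol * max(1, |b|), elementwise, NA-aware (both NA counts as equal)
rel_equal <- function(a, b, tol = 1e-9) {
  if (is.na(a) && is.na(b)) return(TRUE)
  if (is.na(a) || is.na(b)) return(FALSE)
  abs(a - b) <= tol * max(1, abs(b))
}

# Fluid bookkeeping identity on a subject_state (mL).
conservation_gap <- function(state, params) {
  v0 <- reference_volume(params)
  expected <- v0 - state$cum_withdrawn + state$cum_wb_infused +
    state$cum_crystalloid_retained - state$cum_leaked
  abs(state$intravascular_volume - expected)
}
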