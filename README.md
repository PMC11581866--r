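# arcsim

Closed-loop hemorrhage and fluid-resuscitation simulation with adaptive
controllers, in R.

`arcsim` is a desk-scale simulator for *physiological closed-loop control*
(PCLC) of fluid resuscitation in hemorrhagic shock. It couples a synthetic
swine hemodynamic model to two controllers:

- **ARC** — an adaptive resuscitation controller that estimates the subject's
  pressure–volume responsiveness by sliding-window regression and commands an
  infusion rate that drives mean arterial pressure (MAP) upward at a
  configured pace until a permissive-hypotension target is reached, then
  holds it through stabilization and maintenance. A central-venous-pressure
  (CVP) safety rule guards against over-resuscitation.
- **AutoBleed** — a decision-table hemorrhage controller that withdraws (or
  reinfuses) blood to hold a deliberate hypotensive target, banking the
  withdrawn blood with anticoagulant at a fixed 1:7 volumetric ratio so it
  can later be returned as the resuscitation fluid.

Around these it runs a two-event experimental protocol — controlled
hemorrhage to shock, whole-blood resuscitation, a second matched hemorrhage,
and a crystalloid-only resuscitation — and scores each resuscitation event
with the twelve controller-performance metrics conventional in this field
(median performance error and its relatives, band effectiveness, transient
measures, and infusion-rate statistics).

The package is aimed at controls engineers and physiological-modeling
researchers who want a reproducible, fully scriptable test bench for
resuscitation control logic: every run is deterministic given a seed, every
trace and decision log is a plain tibble or CSV, and the whole protocol
simulates in seconds.

## The synthetic subject

The virtual subject is a ~40 kg swine with reference blood volume
V₀ = 70 mL/kg. Its physiology is intentionally minimal — linear where the
real system is approximately linear, and nonlinear only where the fluid
physics demands it:

- **Pressure–volume law.** MAP = MAP₀ + s·(V − V₀) with s = 0.03 mmHg/mL and
  MAP₀ = 65 mmHg, so a 1,000 mL bleed spans 65 → 35 mmHg. Whole blood moves
  intravascular volume one-for-one.
- **Crystalloid kinetics.** Infused crystalloid is retained intravascularly
  with a pressure-dependent fraction (0.80 at or below 45 mmHg, falling
  linearly to 0.25 at or above 65 mmHg); the rest redistributes to the
  interstitium immediately, and retained crystalloid leaks back out in
  proportion to the pressure excess above the lower knee. This makes
  crystalloid resuscitation progressively less efficient as pressure rises —
  the mechanism behind the much larger volumes required in the second event.
- **CVP.** Baseline 5 mmHg, loaded by intravascular excess and by
  interstitial fluid accumulation — so aggressive crystalloid infusion raises
  CVP and can engage the ARC safety rule.
- **Lactate.** Accumulates during ischemia (MAP below 40 mmHg) at an
  anesthetic-stratified rate (4.95 mmol/L/hr ketamine, 2.49 isoflurane), and
  clears — after a 20-minute continuous-reperfusion lag — at 1.0 mmol/L/hr on
  whole blood or 2.0 mmol/L/hr on crystalloid.
- **Hematocrit.** Red-cell mass is tracked separately, so hemorrhage leaves
  hematocrit unchanged while crystalloid dilutes it; banked blood carries the
  bag's (anticoagulant-diluted) hematocrit back in.

All parameters are overridable (`make_subject()`), and a cohort constructor
applies seeded between-subject jitter. See the methods vignette
(`vignettes/arcsim-methods.Rmd`) for every equation, constant, and the
reasoning behind it.

## Worked example

One subject through the full two-event protocol:

```r
library(arcsim)

subject <- make_subject()          # default 40 kg ketamine swine, noise 2 mmHg
result  <- run_protocol(subject, seed = 1)
print(result)
#> <protocol_result> 26388 samples over 439.8 min; first hold 40 min (lactate)
#> resuscitation events scored: 2

as.data.frame(glance(result))
#>   duration_min hold1_min hold1_reason hold2_min volume_event1_mL
#> 1        439.8        40      lactate  40.01667         1023.763
#>   volume_event2_mL target_reached_1 target_reached_2 safety_engaged alive seed
#> 1         7699.671             TRUE             TRUE           TRUE  TRUE    1
```

The first hypovolemic hold ends on the lactate shock criterion after 40 min;
the second hold is duration-matched to it. Whole-blood resuscitation needs
about 1.0 L; the crystalloid-only second event needs about 7.7 L and engages
the CVP safety rule — the expected physiological direction.

Per-event scorecards and the event-1 : event-2 ratio table:

```r
m <- result$metrics
as.data.frame(ratio_table(m[m$event == 1, ], m[m$event == 2, ]))
#>                         metric      event1      event2 ratio arrow
#> 1                         mdpe   1.4114480    8.487916  0.17     ↓
#> 2                        mdape   1.5297813   10.208040  0.15     ↓
#> 3                       wobble   0.8210816    6.772607  0.12     ↓
#> 4                effectiveness  97.0653514   60.503829  1.60     ↑
#> 5  resuscitation_effectiveness  97.0653514   95.705249  1.01     ↗
#> 6             target_overshoot   5.9756310   20.521464  0.29     ↓
#> 7                   area_above 126.7120105  453.534470  0.28     ↓
#> 8                   area_below -78.4755095 -152.964654  0.51     ↘
#> 9                    rise_time   4.8833333   12.866667  0.38     ↓
#> 10             median_infusion   0.0000000    0.000000    NA
#> 11               mean_infusion   7.5740770   51.268477  0.15     ↓
#> 12        infusion_variability  38.8381649  100.601220  0.39     ↓
```

`autoplot(result)` shows the full multichannel timeline; `tidy(result)`
returns the metrics in long format. Cohorts run with
`run_cohort(n, ketamine = ..., isoflurane = ...)`, which aggregates
per-subject lactate-accumulation slopes and metric summaries.

## Command line

A thin CLI wraps the same functions
(`system.file("cli", "arcsim", package = "arcsim")`):

```sh
arcsim simulate --config inst/extdata/example_config.yaml --seed 1 --out runs/demo
arcsim cohort   --n 11 --ketamine 5 --isoflurane 6 --seed 1 --out runs/cohort
arcsim metrics  --trace runs/demo/trace_event1.csv --out runs/demo/e1.txt
arcsim report   --event1 runs/demo/e1.txt --event2 runs/demo/e2.txt
```

Configuration is plain YAML with validated keys; every run directory gets a
manifest (configuration hash, seed, versions) sufficient to reproduce it
bit-identically.

## Package layout

- `R/subject.R` — synthetic subject model (`make_subject`, `step_subject`)
- `R/arc.R` — adaptive resuscitation controller (`arc_config`, `arc_step`)
- `R/autobleed.R` — hemorrhage controller and blood bag (`autobleed_step`)
- `R/protocol.R` — protocol runner and cohorts (`run_protocol`, `run_cohort`)
- `R/metrics.R` — the twelve-metric scorecard (`event_metrics`, `ratio_table`)
- `R/io.R`, `R/cli.R` — CSV/YAML I/O, manifests, and the CLI
- `vignettes/arcsim-methods.Rmd` — model equations, parameter rationale,
  numerical choices, and limitations
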