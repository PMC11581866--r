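---
title: "arcsim methods: model, parameters, and design rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{arcsim methods: model, parameters, and design rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arcsim)
```

This vignette documents the synthetic physiology, the controller designs,
the numerical choices, and the known limits of `arcsim`. It is a methods
reference, not a tutorial; the README holds the worked example. Code chunks
are shown but not evaluated — every quantitative claim made here is either
an analytical statement about the model equations or a value computed by the
test suite (`tests/testthat/`) or the acceptance script
(`scripts/acceptance.R`).

## 1. The synthetic subject

### 1.1 State and pressure–volume law

The subject state tracks intravascular volume $V$ (mL), the intravascular
crystalloid sub-volume $C$, interstitial fluid excess $I$, red-cell volume
$R$, and the derived signals MAP, CVP, lactate $L$, and hematocrit
$H = R/V$. The controlled variable follows a linear pressure–volume law

$$\mathrm{MAP} = \max\!\big(0,\; \mathrm{MAP}_0 + s\,(V - V_0)\big)$$

with $s = 0.03$ mmHg/mL, $\mathrm{MAP}_0 = 65$ mmHg, and
$V_0 = 70\ \mathrm{mL/kg} \times 40\ \mathrm{kg} = 2800$ mL. The slope is
chosen so a 1,000 mL hemorrhage spans 65 → 35 mmHg — the hemorrhage target
band of the protocol — which makes whole-blood responsiveness exactly the
quantity the adaptive controller must discover. Linearity in the whole-blood
direction is a deliberate idealization: it gives the controller a stationary
ground truth, so estimation error is attributable to noise and windowing
rather than to plant drift.

### 1.2 Crystalloid kinetics

Crystalloid infused at rate $q$ for $\mathrm{d}t$ minutes splits between
compartments by a pressure-dependent retention fraction

$$\rho(\mathrm{MAP}) =
  \rho_{\max} - \min\!\Big(1, \max\big(0,
  \tfrac{\mathrm{MAP} - 45}{65 - 45}\big)\Big)\,(\rho_{\max} - \rho_{\min}),
\qquad \rho_{\max} = 0.80,\ \rho_{\min} = 0.25,$$

with the retained part $\rho\,q\,\mathrm{d}t$ entering $V$ (and $C$) and the
remainder going directly to $I$. Retained crystalloid then leaks to the
interstitium at

$$\mathrm{leak} = k_\ell \,\max(0, \mathrm{MAP} - 45)\, C\,\mathrm{d}t,
\qquad k_\ell = 0.004\ \mathrm{min^{-1}\,mmHg^{-1}},$$

clipped to $C$. Two consequences drive the second resuscitation event:
crystalloid efficiency falls threefold as MAP rises across the retention
ramp, and fluid already given continues to escape, so maintenance requires
ongoing infusion. At the resuscitation target the equilibrium is a running
balance between commanded inflow and pressure-proportional leak — the model's
version of the large crystalloid volumes and rising CVP seen in practice.

### 1.3 CVP, lactate, hematocrit

$$\mathrm{CVP} = 5 + 0.004\,(V - V_0) + 0.002\,I \quad \text{(mmHg)}.$$

The baseline (5 mmHg) and both gains are invented constants, set so that (a)
a pure whole-blood resuscitation back to $V_0$ restores CVP to baseline, and
(b) several liters of interstitial crystalloid push CVP through the 15 mmHg
safety threshold — the regime the safety rule exists for. They are not fit
to data.

Lactate accumulates while $\mathrm{MAP} < 40$ mmHg at an
anesthetic-stratified rate (4.95 mmol/L/hr ketamine, 2.49 isoflurane, with
the pooled 3.61 used for the single-subject propofol stratum), and clears
only after MAP has been at or above 55 mmHg *continuously* for 20 minutes —
a lag clock that resets on any dip below the clearance threshold — at
1.0 mmol/L/hr on whole blood or 2.0 mmol/L/hr on crystalloid, floored at the
baseline 1.0 mmol/L. Accumulation is linear by construction, which is what
makes the cohort lactate-slope target analytically exact: an ordinary
least-squares fit through noise-free 10-minute readings of a linear ramp
returns the ramp rate, so the pooled cohort mean is
$(5 \times 4.95 + 6 \times 2.49)/11 = 3.608$, inside the 0.01 tolerance of
the published 3.61.

Red-cell volume is bookkept separately: withdrawal removes red cells at the
subject's current hematocrit, whole-blood infusion adds them at the source
(bag) hematocrit, crystalloid adds none. Hematocrit is therefore invariant
under hemorrhage and diluted by crystalloid, matching the qualitative in
vivo observation that dilution appears mainly in the crystalloid event.

### 1.4 Parameter summary

| parameter | default | units | rationale |
|---|---|---|---|
| `weight` | 40 | kg | mid-range study animal |
| `blood_volume_per_kg` | 70 | mL/kg | standard swine estimate |
| `baseline_map` | 65 | mmHg | equals the resuscitation target (permissive hypotension to the subject's own baseline) |
| `wb_slope` | 0.03 | mmHg/mL | 1,000 mL bleed spans 65→35 mmHg |
| `crystalloid_retention_max/min` | 0.80 / 0.25 | — | ~3–4:1 crystalloid:blood replacement at pressure, near 1:1 in deep shock |
| `retention_knee_low/high` | 45 / 65 | mmHg | ramp spans the protocol's pressure range |
| `leak_rate` | 0.004 | /min/mmHg | invented; sets maintenance-phase crystalloid demand |
| `baseline_cvp`, `cvp_volume_gain`, `cvp_interstitial_gain` | 5, 0.004, 0.002 | mmHg, /mL, /mL | invented; see §1.3 |
| `lactate_accum_rate` | 4.95 / 2.49 / 3.61 | mmol/L/hr | anesthetic strata (propofol = pooled) |
| `lactate_clear_rate_wb/crystalloid` | 1.0 / 2.0 | mmol/L/hr | final-hour clearance rates by infusate |
| `clearance_lag`, thresholds | 20; 40, 55 | min; mmHg | lagging-indicator behavior of lactate |
| `baseline_lactate`, `baseline_hct` | 1.0, 0.30 | mmol/L, — | invented plausible baselines |
| `noise_sd` | 2 | mmHg | arterial-line measurement noise |

`make_subject()` validates every override; `run_cohort()` can apply seeded
multiplicative jitter to `wb_slope`, `baseline_map`, `baseline_hct` and
`lactate_accum_rate` for between-subject variability.

## 2. The adaptive resuscitation controller

Every `control_interval` (10 s) the controller:

1. filters the raw MAP samples of the last `filter_window` (10 s) — median
   after rejecting samples more than 20 mmHg from the window median
   (artifact rejection for blood draws and line flushes);
2. applies the CVP safety rule (§2.2);
3. appends (cumulative infused volume, filtered MAP) to its history and
   re-estimates responsiveness $\hat{s}$ as the ordinary least-squares slope
   of MAP against volume over the trailing `regression_window` (180 s),
   falling back to `bootstrap_slope` (0.03 mmHg/mL) when the window holds
   fewer than two distinct volumes or spans less than `min_dv` (5 mL);
4. commands $Q = \mathrm{pace}/\max(\hat{s}, \text{slope floor})$, clamped
   to $[q_{\min}, q_{\max}]$ — the rate at which a subject of responsiveness
   $\hat{s}$ rises at the configured pace (6 mmHg/min).

### 2.1 Engagement hysteresis

A literal "infuse iff MAP < target − deadband" rule chatters at the band
edge and parks the subject 2 mmHg under the target, which is incompatible
with holding the target itself. The stateful controller therefore uses
hysteresis: it infuses until filtered MAP *reaches* the target, then idles
until MAP falls below target − deadband. The exported stateless primitive
`compute_rate()` retains the plain deadband semantics (and is tested as
such); `arc_step()` passes its own engagement flag. Attainment also drives
the phase machine: resuscitation → stabilization at first target crossing,
stabilization → maintenance after `stabilization_duration` (10 min), with
the infusate switching from whole blood to crystalloid at maintenance when
the event began on blood.

### 2.2 CVP safety rule

At the first tick with CVP ≥ 15 mmHg the active target drops to the
subject's own baseline MAP (if lower than the current target); while CVP
stays at or above threshold the target steps down a further 2 mmHg every
5 minutes, never below 40 mmHg. The engagement point is exact by
construction — the acceptance sweep feeds CVP 0→20 in 0.1 steps and the
first change occurs at exactly 15.0.

### 2.3 Two deviations from the obvious defaults, and why

**Pump ceiling $q_{\max} = 250$ mL/min.** The rate law must be able to
command $Q = \mathrm{pace}/s = 6/0.03 = 200$ mL/min on the default subject —
that is precisely the rise-pace target the acceptance suite checks. A
150 mL/min ceiling would saturate the pump on the nominal plant and cap the
rise at 4.5 mmHg/min, making the configured pace unreachable. The ceiling is
set above the nominal operating point with headroom for subjects up to ~25%
less responsive; stiffer safety is available by configuration.

**Regression window 180 s, not 60 s.** With ticks every 10 s, a window of
$w$ seconds holds $n = w/10$ points. For an OLS slope through equally spaced
volume increments $d$ (mL/tick) with per-tick filtered-noise standard
deviation $\sigma$, the slope standard error is
$\sigma / \big(d\sqrt{n(n^2-1)/12}\big)$. Under the running controller the
per-tick MAP increment is $s \cdot d = \mathrm{pace} \times 10/60 = 1$ mmHg
regardless of $s$, and the median-of-10 filter at noise 2 mmHg leaves
$\sigma \approx 2\sqrt{\pi/20} \approx 0.79$ mmHg. At $w = 60$ s
($n = 6$): relative slope s.e. $\approx 0.79/\sqrt{17.5} \approx 19\%$ — a
"90% of estimates within 15%" recovery property is statistically
unattainable. At $w = 180$ s ($n = 18$): $\approx 3.6\%$, comfortably
passing, while remaining short enough (3 min) to track the plant within one
rise phase. The property test in the acceptance suite reproduces exactly
this regime.

## 3. AutoBleed and the blood bag

AutoBleed maps the filtered MAP error $e = \mathrm{MAP} - 35$ to a signed
pump rate from a monotone decision table (0 within the ±2 mmHg tolerance,
then 10 / 25 / 60 mL/min as $|e|$ passes 2 / 4 / 10 mmHg), withdrawing above
target and reinfusing below. The same chattering argument as §2.1 applies at
the band edge, so the controller keeps a 10 mL/min creep rate inside the
tolerance band until the error first crosses zero, then idles until MAP
leaves the band — this is what makes the 30–60 min hold average sit on the
target (the acceptance value is ≈ 35.0) rather than at the band edge.

Withdrawn blood is banked with CPDA-1 anticoagulant at a fixed 1:7
volumetric ratio. The bag is a three-component mass balance (blood,
anticoagulant, red cells); its hematocrit is red-cell volume over total
mixed volume, reinfusion draws all components proportionally (leaving bag
hematocrit unchanged), and reinfusing more than the bag holds is an error.
Because every withdrawal step adds blood and anticoagulant in exact ratio,
the 1:7 invariant holds to rounding over any simulated schedule — the
acceptance suite asserts it at 10⁻⁹ relative.

## 4. Protocol, cohort, and problem sizes

The full protocol runs: 30 min baseline; hemorrhage to the 35 ± 2 mmHg band;
hypovolemic hold until a 10-min-cadence lactate reading reaches 4 mmol/L or
90 min elapse; whole-blood ARC resuscitation to 65 mmHg with 10 min
stabilization and 120 min crystalloid maintenance; a second hemorrhage and
duration-matched hold (cut short if lactate reaches 6 mmol/L); and a
crystalloid-only resuscitation with the same stabilization/maintenance
schedule. Holds are matched by realized first-hold duration, shock is
declared at the reading (not between readings), and all event boundaries are
recorded in `result$events`.

Typical sizes: one protocol run simulates ~400–440 min at 1 s steps
(~25,000 state updates, ~2,500 control ticks) in a few seconds of wall
time; the acceptance script (five targets, including an 11-subject truncated
cohort) completes in well under a minute; the full test suite, including a
1,000-trace metric-oracle sweep and a full protocol run, takes under a
minute. The 15-minute runtime criterion is met with two orders of magnitude
of margin.

## 5. Numerical choices

- **Time step.** Fixed $\mathrm{d}t = 1$ s (1/60 min), explicit Euler. The
  stiffest dynamic is the leak term with rate constant
  $k_\ell \cdot \max(\mathrm{MAP}-45) \lesssim 0.24\,\mathrm{min^{-1}}$, so
  the step is ~250× below the stability limit and discretization error is
  negligible against the stated tolerances.
- **Medians and ties.** All medians (filter and Varvel metrics) are
  `stats::median`: even-length windows average the middle pair. The
  artifact-rejection filter falls back to the plain median if rejection
  would discard every sample.
- **Areas.** Trapezoidal integration (`pracma::trapz`) of the positive and
  negative parts of (MAP − target), matching the loop-based oracle to 10⁻⁹.
- **Variability.** Sample standard deviation (n − 1), defined as 0 for a
  single sample; empty series are errors, never NaN.
- **Degenerate inputs.** Empty filter windows, non-positive targets, empty
  traces, non-monotone or non-uniform trace time axes, unknown YAML keys,
  over-draining the bag, commands beyond the pump limit, and stepping a dead
  subject all raise immediate, specific errors rather than propagating NA.
- **Determinism.** A single seed fixes a protocol run; cohort subject $i$
  uses seed $\text{base} + i$. Jitter draws restore the caller's RNG state.
  Noise-free configurations are exactly reproducible across seeds.

## 6. Realism and limitations

The generator is a test bench, not a patient simulator:

- **No compensation or drift.** Real subjects vasoconstrict, re-fill from
  the interstitium, and drift hemodynamically; the synthetic subject is
  stationary between commands. Closed-loop control is therefore *cleaner*
  than in vivo: in the demonstration cohort the signed bias (MDPE) matches
  the in vivo benchmark almost exactly, while MDAPE, wobble, and overshoot
  fall below the in vivo ±1 SD bands. Those comparisons are calibration
  context, not validation claims.
- **No cardiac output, SvO₂, or SVV channels.** CVP is a two-gain
  surrogate; the safety rule's *logic* is fully exercised, but its
  engagement timing in a real subject would differ.
- **Mortality is volumetric only.** The subject dies only by exsanguination
  ($V \le 0$); there is no ischemic or arrhythmic death model, so maximal
  holds are survivable by construction.
- **Crystalloid spiral.** Under default parameters the crystalloid
  maintenance phase settles into a leak-replacement equilibrium with rising
  CVP that reliably engages the safety rule and walks the active target
  down. This is the intended qualitative behavior (large volumes, high CVP)
  but its magnitude is set by the invented leak and CVP gains, not by data.
- **Lactate kinetics are piecewise linear** with a hard threshold and lag;
  real clearance is smoother and perfusion-dependent.

Within those limits, every acceptance quantity is either exact by
construction (CPDA ratio, safety threshold), analytically derived from the
model (pooled lactate slope), or a direct closed-loop measurement with an
a-priori tolerance (rise pace, hold and stabilization averages).
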