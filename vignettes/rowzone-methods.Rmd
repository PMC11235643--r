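---
title: "Heart-rate zone analysis of on-water rowing data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate zone analysis of on-water rowing data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rowzone)
```

`rowzone` analyses the three signals a rowing crew records every second on
the water — stroke rate (SR, strokes per minute), boat velocity (m/s) and
heart rate (bpm) — and turns them into training-intensity summaries that
can be compared across athletes, sessions and months. This vignette
explains the models behind each stage, the defaults and why they were
chosen, and what the synthetic-data generator can and cannot tell you
about real data.

## 1. From a step test to five heart-rate zones

Each athlete's intensity scale is anchored in an incremental ergometer
test: seven four-minute steps of increasing power, with blood lactate
sampled after each step and heart rate recorded throughout. Three models
turn this table into a personal five-zone heart-rate scheme:

1. **Lactate curve.** Lactate concentration is regressed on power with a
   least-squares cubic polynomial — smooth enough to support threshold
   geometry, flexible enough to track the accelerating rise. Duplicate
   step powers make the design rank-deficient and are refused.
2. **LT1 (first lactate threshold)** is the lowest power at which the
   fitted curve exceeds its baseline by 0.4 mmol/L. The baseline is the
   fitted curve value at the first step power (default), so the rule is
   self-consistent on the curve being searched; the observed first-step
   lactate can be selected instead (`lt1_baseline = "observed"`). The
   crossing is located by a 0.1 W grid scan refined by bisection, ties
   resolving to the lower power.
3. **LT2 (second threshold, modified D-max)** is the power maximising the
   perpendicular distance between the fitted curve and the chord from the
   LT1 point to the final step point. Anchoring the chord at the first
   rise rather than the first data point is what makes the construction
   the "modified" variant. The argmax is found by exhaustive search on a
   0.1 W grid; distances are computed in raw axis units (W on x, mmol/L
   on y). D-max-type constructions are not scale-invariant; keeping raw
   units matches the conventional implementations, and the grid/tie
   conventions are fixed so results are exactly reproducible.

Heart rates at power landmarks come from piecewise-linear interpolation of
step mean heart rate against step power — the simplest mapping that passes
through every measured step; extrapolation outside the tested range is
refused rather than guessed.

The five zones T1..T5 are then anchored at four heart rates: 50% VO2peak,
LT1, LT2 and 100% VO2peak. T1 runs from 50% VO2peak to the midpoint
between 50% VO2peak and LT1; T2 up to LT1; T3 up to 95% of LT2; T4 up to
102% of LT2; T5 up to 100% VO2peak. Two conventions needed fixing:

* **95%/102% act on the heart rate at LT2** (default). Applying them to
  LT2 *power* first and interpolating the result to heart rate is
  available via `pipeline_config(lt2_scale_on = "power")`; with a locally
  linear HR-power response the two differ little, but the HR reading keeps
  the zone model self-contained in heart-rate units.
* Zone intervals are **upper-inclusive** (`(lo, hi]`), with T1 also
  including its lower bound, so every heart rate in range belongs to
  exactly one zone.

A worked example: landmarks 120/150/180/200 bpm give boundaries
120, 135, 150, 171, 183.6, 200.

```{r}
build_zone_model(lt1_hr = 150, lt2_hr = 180, hr50 = 120, hr100 = 200)
```

## 2. The cleaning cascade

Raw 1 Hz streams contain drills, turns, stationary race starts, and
sensor noise. The cascade applies, in order: a stroke-rate band
(14–50 spm, inclusive); a 15 s trailing moving average on velocity (the
first 14 samples use the expanding mean, so the output starts immediately);
a smoothed-velocity band (2.1–7.0 m/s); conversion to prognostic velocity
(percent of the senior world-best velocity for the boat class and sex);
zone classification with below-T1 data dropped; a gradient filter; and a
minimum-run filter. Per-stage removal counts are kept, and always sum
exactly to raw minus surviving records.

Choices worth knowing about:

* **Trailing (causal) smoothing** mirrors what a device computes in real
  time and never uses future samples.
* The **gradient filter** removes a record when stroke rate changed by at
  least 1.5 spm versus the record 5 s earlier **and** smoothed velocity
  changed by at least 0.2 m/s versus the record 3 s earlier. References
  are resolved by timestamp; a reference missing because of a gap or an
  earlier removal disables that condition. The conjunction is
  configurable (`grad_connective = "or"`); the two readings differ mainly
  on pure ramps of a single variable.
* The **minimum-run filter** deletes every maximal run of identical zone
  labels shorter than 15 points. Its purpose is the heart-rate lag: at the
  start of a harder effort the heart rate briefly transits lower zones,
  and those seconds carry a stroke rate that belongs to the new effort,
  not to the zone they are momentarily labelled with.
* Heart rates **above the T5 ceiling are clamped into T5** by default:
  supramaximal readings still represent maximal-intensity work. Dropping
  them instead is one switch away (`above_t5 = "drop"`). Below-T1 data is
  always dropped — easy paddling carries no intensity information here.
* World-best velocities are **configuration, not constants**. The packaged
  table approximates public 2000 m world-best paces; serious use should
  supply the current official table (`read_world_best()`).

The filter order follows the order in which the steps are described
above; the order is part of the configuration surface in the sense that
re-ordering (for example min-run before gradient) measurably changes
retention on artifact-laden sessions, which the tests pin down.

## 3. Statistical surfaces

* **Session-by-zone summary**: arithmetic means of stroke rate and
  prognostic velocity per (athlete, session, zone).
* **Overlapping index** eta-hat between two zones' distributions: the
  integral of the pointwise minimum of two Gaussian-kernel density
  estimates. Bandwidths follow Silverman's rule per sample; both densities
  are evaluated on a common 1024-point grid spanning the joint range
  extended by three bandwidths; the trapezoidal integral is clipped to
  [0, 1]. For two equal-variance normals separated by delta the index has
  the closed form 2 * Phi(-|delta| / (2 * sigma)), which the tests use as
  an independent oracle (≈ 0.3173 at delta = 2, sigma = 1).
* **Zone contrasts**: `response ~ zone + (1 | athlete_id)` fitted by REML
  with `lmerTest`, estimated marginal means via `emmeans`, all ten
  pairwise zone differences with 95% confidence limits, Satterthwaite
  degrees of freedom for the raw p-values and Benjamini–Hochberg
  adjustment across the ten contrasts. A single athlete makes the random
  intercept unidentifiable; the model then falls back to a fixed-effects
  `lm` with a warning.
* **Stroke-rate bins** (single scull only): 14–18, 19–21, ..., 46–50 spm,
  closed on both printed ends, with stroke rate rounded to the nearest
  spm before lookup, then per-session bin means.
* **Correlation**: Pearson r with the conventional magnitude scale
  (trivial < 0.1 ≤ small < 0.3 ≤ moderate < 0.5 ≤ large < 0.7 ≤ very
  large < 0.9 ≤ nearly perfect < 1 = perfect). A boundary value takes the
  higher category, so r = 0.50 reads "large". Per-athlete coefficients are
  computed within athlete on the same rows.
* **Progression at 20 spm**: per-session mean prognostic velocity over the
  19–21 spm window, correlated against days since the first session.

## 4. The synthetic-data generator

No on-water dataset ships with the package, so the generator produces
cohorts with known ground truth against which every stage is testable.

* **Step tests** follow an exponential lactate curve
  La(P) = a + b·exp(c·P) and a linear, ceiling-clipped HR–power response;
  VO2peak landmarks come from a linear oxygen-uptake model. Defaults by
  sex give LT1 near 160 bpm, LT2 near 180 bpm and peak aerobic power near
  440 W (men) / 285 W (women) — representative of highly trained under-23
  rowers. Measurement noise defaults: 0.15 mmol/L (lactate), 2 bpm (step
  heart rate). Occasionally noise pushes the detected landmarks out of
  order (about 5% of draws); cohort generation then redraws that
  athlete's test, as a re-test would in practice.
* **Sessions** are built from segment templates (duration, target stroke
  rate, intended zone). Within a segment, stroke rate is target plus
  Gaussian noise (0.8 spm); velocity follows the power law
  v = k·SR^e (defaults k = 0.675, e = 0.55 for men in the single scull,
  giving ~68% of world best at 20 spm and ~87% at 31 spm) scaled by a
  boat-class speed ratio, an environmental multiplier (uniform 0.94–1.06
  across sessions) and 2% multiplicative noise; heart rate follows the
  first-order lag dHR/dt = (HR_target − HR)/tau with tau = 30 s, the
  conventional time constant for the on-transient of heart rate.
* **Artifacts** arrive at a configurable per-minute rate (default 0.5):
  drill/turn blocks (stroke rate 6–12 spm, near-stationary boat, heart
  rate relaxing towards rest) and stationary race starts (8–12 s holding
  at the line, then a 10–15 s wind-up from 16 to 40 spm at maximal
  effort). Race starts are concentrated in race-practice sessions
  (40% of that template's artifacts, 2% elsewhere), since crews rehearse
  starts, they do not sprinkle them through aerobic work.
* **Cohorts** draw athlete-level effects — a log-normal multiplier on the
  velocity coefficient k (SD 0.03) and an additive offset on heart-rate
  targets (SD 3 bpm) — the minimal heterogeneity that makes a random
  athlete intercept meaningful. Session target stroke rates are jittered
  per segment (±1.5 spm) to emulate day-to-day variation in prescribed
  rate bands. Boat classes are sampled from a configurable frequency
  table dominated by small boats; dates spread uniformly over a 120-day
  observation window; an optional fractional velocity trend per day
  models a fitness change (default 0 — no trend).

### What the generator does and does not emulate

It reproduces the *structure* that the pipeline's claims rest on: ordered
zone-wise stroke rate and velocity, heart-rate lag, artifact
contamination, athlete heterogeneity and environmental velocity scaling.
It does **not** model stroke-by-stroke mechanics, GPS noise of a specific
device, water or weather dynamics, crew interactions, or fatigue within a
session. Passing tests on synthetic cohorts therefore demonstrate that the
algorithms do what they claim under known conditions — not that real
on-water data satisfies those conditions.

Two behaviours of the full system are worth flagging:

* **Surviving race-start fragments.** A handful of seconds at the end of
  each stationary start can survive the cascade: their gradient-filter
  lookback references were themselves removed (band filters), which
  disables the gradient conditions, and the slowly descending heart rate
  after the effort keeps the zone run longer than 15 points. These
  fragments carry high stroke rate with low smoothed velocity, and in the
  sparse top stroke-rate bins they can appear as near-singleton
  session-bin rows. Their main visible effect is to attenuate the
  session-bin-level SR–velocity correlation relative to the strongly
  positive relationship in the artifact-free records; the same leakage
  mechanism exists for any cascade with these reference semantics.
* **Joint coverage of mixed-model recovery.** With a random athlete
  intercept, the deviation of every estimated zone mean from the
  generating truth is dominated by one shared quantity — the realised
  mean of the athlete intercepts — whose uncertainty the model's standard
  errors correctly report. Each zone mean individually lies within 2 SE
  of truth with the nominal ~95% probability, but the *joint* event that
  all five do cannot be more probable than the marginal one (empirically
  ~87% at 16 athletes). Tests of recovery should therefore be read
  per-estimate, or on the zone differences, where the shared term
  cancels.

## 5. Problem sizes and numerical conventions

The test suite simulates at sizes chosen to make each check sharp while
staying quick: filter oracles on one hundred 600 s fixtures; threshold
recovery on a 3 × 3 grid of lactate-curve parameters; the overlap oracle
at n = 50,000 per sample (KDE bias at Silverman bandwidths is ~0.004,
well inside the ±0.01 check); mixed-model recovery on 20 cohorts of 16
athletes × 30 sessions; cohort-scale structure on 8 athletes × 8
full-length sessions; progression nulls on 20 cohorts of 8 athletes × 15
short single-scull sessions, sized so the 20-seed mean correlation has a
standard error near 0.02. All randomness is seeded; identical seeds give
bit-identical streams, summaries and files.

Tie-breaks and edge rules, in one place: band bounds inclusive on both
ends; zone intervals upper-inclusive with T1 lower-inclusive; heart rates
above T5 clamped (configurable); threshold searches resolve ties to the
lower power; correlation magnitudes resolve boundary values upward;
missing gradient references disable their condition; runs are maximal
blocks of identical zone labels; empty cleaned sessions warn rather than
fail.

## 6. Known limitations

* Thresholds depend on the cubic lactate fit; with fewer than six
  informative steps or strongly non-monotone lactate readings the D-max
  geometry degenerates (flagged by a boundary warning rather than
  silently accepted).
* The prognostic scale inherits whatever world-best table is supplied;
  comparisons across eras need a consistent table.
* The gradient filter cannot see rapid changes whose reference records
  were removed earlier in the cascade (see above).
* Retention fractions on synthetic cohorts (roughly 50–60% at default
  artifact rates) describe the generator's contamination level, not any
  particular device or crew.
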