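---
title: "Methods: quantifying foot-placement modulation and force-field effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying foot-placement modulation and force-field effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpmod)
```

## The measurement problem

Walkers stabilize themselves laterally in part by choosing where to put
the next foot: when the pelvis is displaced or moving away from the
stance foot at the start of a step, the upcoming step tends to be
wider. `fpmod` estimates the strength of that coupling — the partial
correlation ρ_disp between step width and mediolateral pelvis
displacement, controlling for mediolateral pelvis velocity — from
treadmill motion capture, and models how a mediolateral force-field
(assisting or perturbing the swing leg) changes it. In chronic stroke
the coupling is typically weaker for paretic steps, which is why the
per-side estimate and the 0.56 baseline eligibility screen exist.

The pipeline is: read markers → low-pass filter → detect gait events
from heel AP velocity → per-step spatial metrics and pelvis state over
normalized step time → per-minute ρ_disp and metric means → period
aggregation → paired comparisons.

## Model and assumptions

ρ_disp is a linear (Pearson) partial correlation with a single control
regressor, the pelvis velocity; it assumes an approximately linear
step-to-step relation between pelvis state and the realized step width
within an analysis window, and stationarity within each one-minute
window. It makes no distributional assumption beyond finite variances;
the paired inference layer is fully nonparametric (Wilcoxon signed
rank).

Every mediolateral quantity shares one signed convention, fixed per
step: positive is the direction from the stance heel toward the
swing-leg side. This makes "wider step when the pelvis is farther/
faster away from the stance foot" a positive relationship for both left
and right steps, keeps crossover steps informative as negative widths
(summaries average signed values, so crossovers are not folded into
the mean), and means mirroring a whole trial left–right changes no
metric value — a property the test suite checks exactly.

Pelvis displacement within a step is referenced to the *instantaneous*
stance-heel ML position rather than its position frozen at step start.
The stance heel is nominally stationary in ML during its stance, and
the instantaneous choice keeps the normalized-time-0 sample identical
to the `x_pelvis` used by the controller equation. This was a genuinely
open choice; the frozen-reference variant differs only through stance
heel drift, which the consistency test bounds below 5 mm on rendered
data.

Per-period ρ_disp is the mean of per-minute correlations, not one
pooled correlation over the period's steps — metrics are computed
minute by minute and then averaged, which keeps slow drifts in gait
from inflating the correlation. A pooled estimate over any window
remains available through `rho_curve(metrics, side, window = ...)` and
should be treated as exploratory.

## Gait events

A step starts at the ipsilateral heel's posterior→anterior AP velocity
crossing and ends at the contralateral heel's next such crossing (the
shared event starting the following step). Filtering leaves
micro-oscillations near zero, so a crossing counts only if velocity
stays non-negative for ≥ 50 ms and the previous onset on that heel is
≥ 200 ms older. Candidate steps outside 0.2–2.5 s — comfortably
covering 25–52 steps/min — are dropped and QC-logged, as are onsets
without a following contralateral onset (trial-edge steps have no
width). A step is dated by its end time, in half-open minutes
`[60k, 60(k+1))`, because its width only exists at its end.

## Numerical choices

* **Filter**: 4th-order Butterworth at 10 Hz, applied forward–backward
  for zero net phase (the field convention for gait kinematics; the
  order/family is this package's choice). Edge transients are
  suppressed by odd-reflection padding (1 s), so a constant channel
  passes through bit-near-exactly and gait-band content (≤ ~3 Hz) is
  essentially unchanged.
* **Velocity**: central differences on the uniform grid, one-sided at
  the endpoints — second-order accurate, no added latency.
* **Gaps**: missing samples are linearly interpolated when a run lasts
  ≤ 0.1 s; longer gaps are fatal, since they would invalidate events.
* **Normalized time**: pelvis state at the 101 points comes from linear
  interpolation of the filtered trajectories; a 120 Hz grid rarely
  lands on exact step fractions.
* **Degenerate correlations** (zero variance, a control correlation of
  magnitude 1, fewer than 10 steps of a side in a minute) yield an
  explicit `NA`, never a propagated NaN; such minutes are excluded from
  period means and logged.
* **Paired test**: zero differences are dropped; for ≤ 25 non-zero
  differences the two-sided p comes from the exact null of the signed
  midrank sum, computed by convolution of the rank generating function
  (this stays exact under tied magnitudes, where the textbook
  distribution does not apply); above 25, a normal approximation with
  continuity and tie corrections. Cohen's d is the paired-difference
  form mean(diff)/sd(diff). All-zero differences leave p undefined and
  the contrast non-significant.
* α defaults to 0.025: two primary comparisons (direct effect,
  after-effect) per group. Secondary metrics are reported at the same
  threshold with raw p-values and a `primary = FALSE` flag rather than
  a further correction.

## The force-field controller model

The controller targets `SW* = A·x_pelvis + B·SW_mean` with
speed-dependent coefficients on a 0.2–1.2 m/s grid, linearly
interpolated and clamped to the grid ends (speeds below 0.2 m/s use the
0.2 m/s entries), and renders the target as a 180 N/m spring on the
swing leg. Numeric coefficient values for real hardware are a required
configuration input (JSON schema in `read_schedule_json()`); the
shipped `default_schedule()` is explicitly an illustrative stand-in
(assist A decreasing 1.5→1.0 over the grid, perturb A its negation,
B = 1) with the right qualitative structure for simulation and tests,
not an empirical fit. Swing-leg dynamics are abstracted into one
compliance gain g ∈ [0, 1]: realized width = intended + g·(target −
intended). Forces act on both legs' swing phases; transparent mode sets
target = actual so the net force is zero by construction.

Under this abstraction the effective displacement coupling of realized
widths becomes `(1−g)β_d + gA`, so a perturbing schedule (A < 0) lowers
measured step-start ρ_disp and an assistive one (A > 0) raises it, for
any g ∈ (0, 1) — the directional analogue of the experimental design,
which the acceptance checks verify on 100 seeded replicates each.

## The synthetic generator

`simulate_steps()` draws, per step and side, a jointly Gaussian pelvis
start state (d, v) and a width `SW = β₀ + β_d d + β_v v + ε`. The true
step-start partial correlation is closed-form:
ρ\* = β_d σ_{d|v} / √(β_d² σ²_{d|v} + γ²σ_d² + σ_ε²) with
σ²_{d|v} = σ_d²(1 − corr_dv²) and γ the optional `coupling_ramp`
weight on the upcoming pelvis end state. `params_for_rho()` inverts
this to hit any target ρ\*.

`render_trajectories()` turns the table into 120 Hz markers. Heel AP
velocity is −belt speed in stance plus a raised-cosine anterior pulse
in swing, constructed so the zero crossing falls exactly at the
programmed onset; heel ML moves to each programmed placement during the
airborne window with a half-cosine; the sacrum ML path is a cubic
Hermite spline through every programmed (d, v) anchor relative to the
stance heel. All content is band-limited far below the 10 Hz cutoff,
so filtering is near-lossless and programmed events and metrics are
recoverable to within a sample and a few millimetres — the tolerances
the closed-loop tests assert. Swing occupies 40% of the step period;
configurations leaving an airborne window shorter than two samples are
rejected as infeasible.

Defaults are a "chronic-stroke-like" preset, chosen once as plausible
for slow hemiparetic treadmill walking and labeled illustrative:
cadence 40 steps/min (the 25–52 range is enforced), belt 0.4 m/s,
3-minute trials, β₀ = 0.12 m, paretic β_d = 0.45 vs non-paretic 0.75
(true step-start ρ\* ≈ 0.48 and 0.68 — a weakened paretic coupling that
passes the 0.56 screen), β_v = 0.10 s, σ_ε = 15 mm, pelvis state SDs
20 mm and 0.05 m/s with correlation 0.4 and means 60 mm and 0.02 m/s.
Step width means then sit near 0.15 m, in the range typical of this
population.

What the generator emulates: the event-defining velocity structure,
per-side linear pelvis→width coupling, realistic cadences and belt
speeds, protocol structure (3 + 3 + 2+1 minutes with the catch minute),
controller action through the compliance gain, and an optional
after-effect as a β_d shift during the catch minute. What it does not
emulate: within-step pelvis autocovariance beyond the Hermite
interpolation (the real structure is unknown and would change the
middle of the ρ_disp curve, though not its endpoints' definitions),
foot-position feedback (absolute foot placement random-walks, as
step-width dynamics without position control do), soft-tissue and
marker noise, double support timing, or any musculoskeletal dynamics.
Passing closed-loop tests therefore demonstrates estimator and pipeline
correctness under the stated model — not that the model is a complete
account of human gait.

An emergent (and physiologically sensible) property of the rendering
is that ρ_disp rises toward step end: the pelvis state at step end is
kinematically linked to where the foot was just placed, so the
step-end correlation exceeds the step-start one even without an
explicit ramp; `coupling_ramp > 0` strengthens this.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use: 1,000 random instances
(n ∈ [5, 50]) for the oracle-equivalence check at 1e-12; 10⁶ steps for
analytic-vs-Monte-Carlo agreement at 0.005; 200 rendered 3-minute
trials at 40 steps/min spanning ρ\* ∈ {0, 0.3, 0.56, 0.8} for recovery
coverage against 95% Fisher-z intervals; a 3 × 3 cadence × belt-speed
grid of 60 s trials for event timing; 100 seeded replicates per
controller direction; and 10,000 null simulations at n = 10 for the
size of the paired test. These sizes were chosen to give stable Monte
Carlo estimates at desk scale.

One calibration note: the exact signed-rank test is discrete. At
n = 10 pairs the largest attainable two-sided size not exceeding
α = 0.025 is 2·P(V ≤ 5) = 0.0195, so the empirical rejection rate of a
correctly implemented exact test sits just below 0.02 — a property of
the test, not an implementation artifact.

## Known limitations

* ρ_disp is correlational; the package does not model the causal
  swing-leg dynamics, and the compliance-gain abstraction compresses
  all actuator and limb mechanics into one number.
* Period aggregation assumes 3-minute trials in the shipped protocol
  schedule; other layouts need a custom schedule table.
* The C3D capture format is not read directly; convert to TRC or the
  wide CSV dialect first.
* Group-level power at n = 10 per group is limited, and below n = 7
  pairs no exact signed-rank result can reach α = 0.025 at all.
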