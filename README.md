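# fpmod — mediolateral foot-placement modulation in treadmill gait

`fpmod` quantifies how tightly walkers couple their step width to the
motion of their pelvis, and how external mediolateral forces change that
coupling. It is aimed at gait and rehabilitation researchers working
with treadmill motion-capture data — in particular studies of people
with chronic stroke, whose paretic steps often show a weakened link
between pelvis motion and foot placement — and at methodologists who
need a fully synthetic, ground-truthed test bed for this family of
analyses.

## The statistic

During steady walking, a step that begins with the pelvis displaced far
(or moving fast) away from the stance foot is normally followed by a
wider step. The package's primary outcome is the partial correlation

ρ_disp = corr( SW , d | v )
       = ( r_SW,d − r_SW,v · r_d,v ) / √( (1 − r_SW,v²)(1 − r_d,v²) )

between the signed step width `SW` and the mediolateral pelvis
displacement `d` from the stance heel, controlling for the mediolateral
pelvis velocity `v`. Pelvis state is sampled at 101 normalized time
points across each step, so ρ_disp is a curve from step start (0%,
the primary "step-start ρ_disp") to step end (100%). All three inputs
come from 120 Hz sacrum and heel markers, low-pass filtered at 10 Hz
(4th-order zero-phase Butterworth):

* **step start / end** — the instants the ipsilateral / contralateral
  heel's anteroposterior velocity turns from posterior (belt-driven
  stance) to anterior (swing);
* **step width** — ML distance between the placing heel at step end and
  the stance heel at step start, signed positive away from the stance
  foot (crossover steps are negative);
* **foot placement** — ML distance from sacrum to placing heel at step
  end; **step length** — AP heel separation corrected for belt travel.

A force-field controller model targets, for every step, the width
`SW* = A·x_pelvis + B·SW_mean` (x_pelvis = pelvis displacement at step
start; SW_mean = mean width of the last 50 baseline steps; A, B
linearly interpolated over a 0.2–1.2 m/s speed grid, clamped below
0.2 m/s) and pulls the swing leg toward it with a 180 N/m virtual
spring. Assistive schedules (A > 0) push with the pelvis state,
perturbing schedules (A < 0) against it; transparent mode tracks the
leg so net force is zero. Direct effects (Normal vs Force periods) and
after-effects (Normal vs the transparent catch minute) are compared
with two-sided Wilcoxon signed-rank tests at α = 0.025, with Cohen's d
of the paired differences reported alongside.

Because real participant recordings are not redistributable, the
package ships a synthetic gait generator: a step-level linear model
`SW = β₀ + β_d·d + β_v·v + ε` with jointly Gaussian pelvis states and a
closed-form true partial correlation, rendered into continuous 120 Hz
marker trajectories whose programmed events and metrics are emitted as
ground truth. Every pipeline stage is validated closed-loop against it.

## Worked example

Simulate one participant's session in the Perturbing group (3 min
Normal walking, 5 min of perturbing forces, 1 min transparent catch),
render the marker trajectories, and run the full analysis:

```r
library(fpmod)

params   <- gait_params(seed = 7)        # chronic-stroke-like preset
protocol <- simulate_protocol(params, mode = "perturbing",
                              compliance_gain = 0.5, render = TRUE)
analysis <- run_analyze(protocol)
analysis
#> <fpm_analysis>
#> # A tibble: 6 × 8
#>   period  side  n_minutes rho_start rho_end mean_step_width_m mean_step_length_m
#>   <chr>   <chr>     <dbl>     <dbl>   <dbl>             <dbl>              <dbl>
#> 1 Force   nonp…         5    -0.629   0.534             0.120                0.6
#> 2 Force   pare…         5    -0.758   0.228             0.110                0.6
#> 3 Normal  nonp…         3     0.736   0.807             0.169                0.6
#> 4 Normal  pare…         3     0.464   0.757             0.150                0.6
#> 5 Transp… nonp…         1     0.699   0.819             0.163                0.6
#> 6 Transp… pare…         1     0.602   0.680             0.148                0.6

analysis$inclusion
#> # A tibble: 1 × 4
#>   eligible   rho threshold reason
#>   <lgl>    <dbl>     <dbl> <chr>
#> 1 TRUE     0.464      0.56 below threshold
```

Reading the output: during Normal walking this synthetic participant's
step-start paretic ρ_disp is 0.464 — the pipeline's estimate of the
generator's true value of 0.482 for this preset, and below the 0.56
eligibility threshold used to select participants with a weakened
coupling. While perturbing forces are applied the coupling inverts
(−0.758: the controller pushes the leg against the mechanically
appropriate placement), and in the transparent catch minute it returns
toward baseline (0.602). `autoplot(rho_curve(...))` draws the ρ_disp
curve over normalized step time; `run_group_study()` runs the paired
direct-effect and after-effect contrasts across a cohort of such
analyses.

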