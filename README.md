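# crossgaze

Simulation and analysis of a roadside psychophysics experiment: a
pedestrian standing at a virtual curb watches a car approach at constant
speed for exactly 3 s and, in a two-interval forced-choice (2IFC) task,
judges either which of two approaches was **faster** or which vehicle
would have **arrived earlier** at the crossing, while gaze is tracked at
high rate. The package is for vision and traffic-safety researchers who
want the complete analysis chain for such data — and a synthetic-data
generator with ground truth to validate every stage without any real
recordings.

## What it computes

* **Scene and design** — constant-velocity approach kinematics on a
  9 × 9 grid of speeds (10–90 km/h) and times-to-arrival (1.44–4.64 s)
  around a 50 km/h / 3.04 s standard; with a fixed 3 s display the start
  and end distances are forced to `d_start = v(3 + T)` and
  `d_end = v·T`, making vehicle position an informative cue. Pinhole
  projection to screen coordinates, dynamic vehicle area of interest
  (AOI), randomized 243-trial sessions.
* **Synthetic observer** — smooth pursuit at a sampled gain with
  catch-up and spontaneous saccades, habitual gaze offsets, blinks and
  tracker noise (with ground-truth event labels), plus a noisy
  internal-estimate decision model: choices follow the interval with the
  larger weighted-cue estimate, `P(correct) = Φ(Δ/(σ√2))` for the
  differencing rule, with lapses and a second-interval bias.
* **Gaze preprocessing** — saccade detection by velocity (22 °/s plus a
  trailing 40 ms pursuit-adaptive term, capped at 60 °/s) and
  acceleration (5000 °/s²) thresholds; blink handling; linear
  interpolation; the 50% exclusion rules for trials and participants.
* **Gaze metrics** — pursuit gain from 3D angular velocities (cross
  product of consecutive direction vectors, zero-phase 10 Hz Butterworth
  filtering), signed/absolute AOI position deviations, saccade counts
  and amplitudes, crossing-AOI saccades, MAD and double-MAD outlier
  screening.
* **Psychometrics** — maximum-likelihood cumulative-normal fits
  `ψ(x) = γ + (1 − γ − λ)Φ((x − pse)/σ)` with bounded guess/lapse rates;
  JND `(x₀.₇₅ − x₀.₂₅)/2`, Weber fraction JND/standard, bootstrap JND
  standard errors, deviance goodness of fit, interval-bias fits.
* **Cue dominance** — per-participant logistic regressions of choices on
  speed, TTA, start and end distance; general dominance (average
  incremental McFadden R²_M over all predictor subsets, summing exactly
  to the full-model R²_M); a noisy theoretical-observer benchmark.
* **Classification** — paired-Hotelling repeated-measures MANOVA
  (Wilks's Λ with `F = ((1−Λ)/Λ)·((n−p)/p)` on (p, n−p) df);
  radial-kernel SVM decoding of task (leave-one-subject-out CV) and
  observer (tenfold CV) with no-information-rate, binomial and
  permutation tests.
* **Performance model** — logistic mixed model of trial correctness on
  gaze metrics with diagonal random effects for observer, speed and TTA,
  a convergence-driven simplification ladder, and VIF collinearity
  checks.

## Worked example

Simulate one observer's TTA session, fit the psychometric function, and
ask which cues drove the choices:

```r
library(crossgaze)

grid <- design_grid()
par  <- observer_params(participant_id = "P01")
des  <- make_design(grid, "P01", task = "tta", seed = 7)
resp <- simulate_responses(des, par, grid, seed = 8)

pd  <- psychometric_data(resp, "tta")
fit <- fit_psychometric(pd$levels, pd$k, pd$n, n_boot = 200, seed = 9)
fit
#> <psy_fit> pse = 2.897, sigma = 0.781, gamma = 0.000, lambda = 0.099
#>   jnd = 0.608 (se 0.091), deviance = 10.97
weber(fit$jnd, 3.04)
#> [1] 0.1999181

general_dominance(resp$chose_comparison, cue_table(resp))
#> <dominance_result> full-model R2_M = 0.3575
#>  speed    tta  start    end
#> 0.0386 0.1728 0.0597 0.0864
```

Read: this observer discriminates arrival-time differences of about
0.61 s (a Weber fraction of 0.20 of the 3.04 s standard; the bootstrap
SE of the JND is 0.09 s). The dominance decomposition attributes most of
the explainable choice variance to the vehicle's true time-to-arrival
(0.17 of a total R²_M of 0.36), with the start/end distance cues —
which this observer's decision weights deliberately use — contributing
0.06 and 0.09, more than their covariation with TTA alone would give a
pure-rule observer.

The printed group statistic from a two-condition gaze comparison can be
checked directly:

```r
wilks_to_f(0.362, n = 14, p = 9)
#> $f
#> [1] 0.9791283
#> $df
#> [1] 9 5
```

The whole chain — simulation, preprocessing, metrics, psychometrics,
dominance, classification, mixed model — runs end to end with

```r
res <- run_pipeline(run_config(seed = 1))   # desk-scale defaults
```

writing per-stage TSV/JSON outputs and a seed-and-hash manifest to the
configured output directory (`run_config(fast = FALSE)` restores the
full 15-observer, 3-block, 1000 Hz design).

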