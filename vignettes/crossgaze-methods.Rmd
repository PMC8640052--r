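---
title: "Methods: simulating and analysing roadside speed and time-to-arrival discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing roadside speed and time-to-arrival discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossgaze)
```

## The experimental situation being modelled

A pedestrian stands 0.64 m from the curb of a single-lane road 3.36 m
wide, eye height 1.6 m. A car (4.53 x 1.82 x 1.47 m) approaches at
constant speed and disappears after exactly 3 s of viewing; the scene
stays on for another 2 s. In a two-interval forced-choice (2IFC) trial
the observer sees a *standard* approach (50 km/h, remaining
time-to-arrival 3.04 s at offset) and a *comparison* drawn from a 9 x 9
grid of speeds (10-90 km/h) and TTAs (1.44-4.64 s), in randomized order,
and judges either which interval's vehicle was faster (speed session) or
which would have arrived earlier (TTA session). Each session shows all 81
comparisons three times (243 trials). Gaze is recorded at 1000 Hz.

`crossgaze` rebuilds this situation end to end: the geometry and design
(`scene_config()`, `design_grid()`, `make_design()`, `trajectory()`,
`vehicle_aoi()`), a synthetic observer that produces gaze traces and
choices (`observer_params()`, `simulate_gaze()`, `simulate_responses()`,
`generate_dataset()`), and the full analysis chain: event detection and
cleaning, nine per-trial gaze metrics, psychometric fits, cue-dominance
analysis, task/observer classification, and a hierarchical logistic
performance model. `run_pipeline()` chains the stages with per-stage
seeds and a hashed manifest.

## Geometry and projection

The observer's eye is the origin; Y points up-road (towards the
approaching vehicle), X across the road, Z up. The vehicle's front-plane
center travels at lateral offset `curb_gap + road_width/2 = 2.32` m, and
the stopping line is abeam of the observer (Y = 0). With a fixed display
interval, constant speed v and remaining TTA T force the start and end
distances d_start = v (3 + T) and d_end = v T, which is why vehicle
position is an informative (and on this grid *exactly* rank-deficient:
start = 3 v + end) cue for both judgements.

The scene is rendered by a pinhole camera (1280 x 1024) and viewed on a
flat screen spanning about 30 x 25 visual degrees at 0.66 m. Two angle
systems coexist and the package keeps them explicit:

* *world/view angles* — direction of a scene point from the eye in the
  virtual world (`world_to_view_angles()`);
* *screen degrees* — visual angle of the rendered image point for the
  seated observer (`view_to_screen()` and its inverse).

The camera's field of view is not part of the scene's physical
description, so it is a configurable parameter (default 55 degrees
vertical). Because the on-screen magnification depends on it,
`calibrate_fov()` solves for the FOV that maps a known world span to a
measured on-screen span; calibrating a 1.82 m front plane at 50 m
(2.085 degrees of world angle) to a 0.95-degree on-screen span yields
roughly 50.4 degrees. At the default 55 degrees the same plane spans
about 0.86 degrees on screen — the discrepancy is a calibration issue,
not a property of the analysis, and every screen-side quantity is
computed consistently within whichever FOV is configured.

Saccade amplitudes and gaze coordinates are reported in *screen visual
degrees* (eye rotations of the seated observer, via
`screen_eye_direction()`); pursuit gain is computed from directions
back-projected into the virtual world (`screen_to_direction()`), where a
gaze/target *ratio* is insensitive to the common projection scale.

## The synthetic observer

The generator's defaults are the package's statement of the study
conditions; they are chosen once, from the experiment's descriptive
scale, and the test suite treats them as fixed.

**Gaze.** Per trial a pursuit gain is drawn from Normal(`pursuit_gain_mean`,
`pursuit_gain_sd`); gaze velocity is gain times the target's screen
velocity plus a weak position servo (`error_correction_gain`, default
0.1 /s) towards the observer's *aim point* — the AOI center displaced by
an idiosyncratic habitual offset (`gaze_offset`, default 0.5 degrees
ahead along the motion direction and 0.7 degrees above). Catch-up
saccades fire when the position error exceeds `catchup_threshold` (1
degree); spontaneous re-centering saccades occur at `saccade_rate_bias`
Hz (default 1.0) with landing dispersion `spontaneous_amp_sd` (0.6
degrees). Saccades follow a minimum-jerk profile lasting 20 ms + 2
ms/degree, with a 150 ms refractory period so that events remain
temporally separable. Blinks are Poisson events (0.15 Hz) of 100-300 ms
that invalidate the pupil; white measurement noise of 0.008 degrees RMS
(EyeLink-class) is added per sample. Ground-truth event labels are kept
alongside every trace.

`default_observer_cohort()` draws per-observer parameters (gain ~
N(0.87, 0.1), saccade rate 0.4-1.6 Hz, landing dispersion 0.4-0.9
degrees, gaze offsets with SDs 0.3/0.5 degrees) so that observers are
mutually distinguishable while the two task sessions share generative
parameters — the configuration under which observer identity should be
decodable from trial-level gaze features and the task should not.

**Decisions.** Each interval receives an internal estimate: a weighted
sum of the four cues (speed, TTA, start and end distance), z-scored over
the 81-cell grid, plus Gaussian noise (`internal_noise_sd`). The
interval with the larger estimate wins ("earlier" is encoded by a
negative TTA weight); `second_interval_bias` (default 0.1) is added to
the second interval, reproducing the temporal-order bias typical of 2IFC
data, and lapses (2%) randomize the choice. For a differencing rule the
proportion correct at cue difference delta is Phi(delta / (sigma
sqrt(2))), which is the closed form the recovery tests check. The
default `internal_noise_sd = 0.95` was calibrated so that the default
cohort's fitted JNDs land on the scale a roadside setting produces
(about 17 km/h and 0.74 s with the default multi-cue weights; the
position cues covary with the task cues, so discriminability is better
than the single-cue closed form suggests). Cue weights themselves are
illustrative — no per-participant weights are estimated from any real
dataset — with signs chosen so that position cues help: nearer or
slower-growing distances read as "earlier", larger distances as
"faster".

**What the generator does not emulate.** No learning across blocks, no
head or trunk movement, no main-sequence velocity scaling beyond the
duration rule, no pupil dynamics, and tracker noise that is white rather
than temporally correlated. Passing tests therefore certify the analysis
chain on data with the *statistical structure* the analyses assume, not
performance on any particular real recording.

## Event detection and cleaning

The detector re-implements a velocity/acceleration threshold scheme with
the published parameters: a sample opens a saccade when 2D gaze speed
exceeds 22 deg/s plus a trailing 40 ms mean of non-saccadic speed
(capped so the total never exceeds the 60 deg/s fixup limit), or when
acceleration exceeds 5000 deg/s^2; it closes when both fall back below.
Velocity comes from central differences and acceleration from
differenced velocity, both on unsmoothed samples. Three guards are
deliberate choices the published description leaves open: candidate
events shorter than 6 ms are dropped, events separated by less than 20
ms are merged, and candidates longer than 150 ms are reclassified as
pursuit — which is what keeps sustained 30 deg/s smooth pursuit from
being labelled one endless saccade. Blinks are maximal invalid-pupil
runs padded by 20 ms. Removed samples are linearly interpolated
(idempotent), trials with more than 50% interpolation in either interval
are excluded, and a participant-condition is dropped when more than half
its trials fall.

A practical limit worth knowing: at 100 Hz synthetic sampling the
smallest (~0.5 degree, ~20 ms) saccades span too few samples to cross
the velocity threshold. The package's fast configurations therefore use
250 Hz for any analysis that consumes saccade statistics; 100 Hz remains
available for smoke runs.

## Gaze metrics

Nine features per trial-interval: pursuit gain; relative and absolute
horizontal and vertical deviation from the vehicle-AOI center (relative
horizontal is signed so positive always means *ahead*, in the motion
direction); saccade count and mean amplitude (the first saccade after
vehicle onset is discarded as the initial orienting response); and
counts of saccades landing in the road-crossing AOI before and after
vehicle offset. Two averaging windows are maintained: the final visible
second (2-3 s) for descriptive and classification features — chosen
because the target's retinal speed is greatest there — and the full
visible interval (0-3 s) for the performance model's predictors.

Pursuit gain is the ratio of gaze to target angular speed. Angular
velocity comes from the cross product of consecutive 3D direction
vectors. Numerically, the implementation computes the rotation-rate
*vector*, zero-phase filters its signed components (2nd-order
Butterworth, 10 Hz), projects the gaze rotation rate onto the target's
rotation axis, and averages over the window, excluding interpolated
stretches (padded 60 ms for filter smearing). Filtering and projecting
*signed* quantities matters: averaging speed magnitudes rectifies
zero-mean tracker noise into the numerator, which at the grid's far,
fast corner (target motion below ~0.1 deg/s on screen) can inflate a 0.9
gain several-fold. When the window-mean target speed is below 0.1 deg/s
the gain is reported as undefined (NA) — the same regime the measurement
is known to be unreliable in, whatever the estimator.

Outlier screening uses the MAD criterion with consistency constant
1.4826: symmetric cut-off 3.5, and for the right-skewed saccade count
and amplitude a double-MAD (separate MADs below and above the median)
at 4.5. A zero MAD disables removals on that side with a warning, so
near-constant metrics are never decimated.

## Psychometrics

Responses are pooled onto the comparison-stimulus axis (proportion
"comparison faster" against comparison speed; proportion "later" —
the complement of "earlier" — against comparison TTA, so both curves
rise). The model is psi(x) = gamma + (1 - gamma - lambda) Phi((x -
pse)/sigma) with the PSE constrained to the stimulus range, guess rate
gamma in [0, 0.05] and lapse rate lambda in [0, 0.1], fitted by
maximizing the binomial likelihood with an L-BFGS-B multistart over a 5
x 5 (pse, sigma) grid — the asymptote bounds create local optima that a
single start falls into. The JND is half the distance between the 25%
and 75% points of the *full* function (asymptotes included) and is
undefined when an asymptote swallows a quantile; the Weber fraction
divides the JND by the standard (50 km/h or 3.04 s). Standard errors of
the JND come from a parametric bootstrap (refits warm-started at the
point estimate); goodness of fit is the deviance against the saturated
model with a parametric-bootstrap p (B = 1000 by default). A
likelihood-ratio check against a constant-probability model flags
uninformative (flat) data. Recovery tolerances are quoted on the scale
each parameter lives on: relative for PSE and sigma, absolute
probability points for gamma and lambda, whose true values sit against
the boundary where relative error is not a meaningful quantity.

The interval bias refits the same model on "chose the second interval"
against the second interval's stimulus value; the bias is reported with
a sign convention where positive always means a propensity to pick the
second interval.

## Cue dominance

Per participant-task, a logistic regression predicts choices from the
four standardized cues; fit quality is McFadden's R^2_M = 1 -
logLik(model)/logLik(null). General dominance averages, within subset
size and then across sizes (empty set included), the incremental R^2_M
of adding a predictor to each subset excluding it; by construction the
dominance values sum exactly to the full-model R^2_M. Complete
separation (possible for near-deterministic synthetic observers) is
flagged and handled by a weakly penalized refit via data augmentation.
The benchmark is a theoretical observer applying the task rule to the
noised task cue of *both* intervals (symmetric differencing;
configurable), with noise taken from the participant's fitted
psychometric sigma — any dominance this observer grants to position cues
reflects only the grid's built-in covariation, so participant dominance
above it indicates genuine cue overuse.

## Classification and the task comparison

The task comparison is a repeated-measures MANOVA in its paired
one-sample Hotelling form on the per-participant task-mean features: T^2
= n dbar' S^-1 dbar, Lambda = 1/(1 + T^2/(n-1)), F = ((1 -
Lambda)/Lambda)((n - p)/p) on (p, n - p) degrees of freedom, with paired
univariate F(1, n-1) tests per feature. The tests verify this transform
against an independent determinant identity (Lambda = det(E)/det(E+H))
and the printed-value check Lambda = 0.362, n = 14, p = 9 gives F(9,5) =
0.98.

Decoding uses a radial-kernel SVM (cost 1, kernel width 1/p on features
z-scored with training-set statistics only): leave-one-subject-out
cross-validation for the task label (mean of per-left-out accuracies,
no-information rate from each test set's majority class, one-sided
binomial test against it) and seeded tenfold cross-validation for
observer identity. Permutation tests re-run the same cross-validation
under label permutations — task labels within participant (respecting
exchangeability), observer labels globally — reporting the one-sided
fraction of permuted accuracies at or above the observed one; an exact
zero is reported as "< 1/n_perm".

## The performance model

Trial-level correctness in each task is modelled by a logistic mixed
model: the seven full-interval gaze metrics (standardized; scaling
recorded) as fixed effects, and observer, comparison speed and
comparison TTA as categorical random factors with *diagonal* covariance
(slopes uncorrelated with intercepts), estimated by Laplace-approximate
ML via lme4. The simplification ladder tries (1) uncorrelated intercepts
and slopes for all three factors, (2) slopes for the observer only, (3)
intercepts only, stopping at the first rung that converges and recording
the log-likelihood/AIC of the next-simpler rung for comparison; if
nothing converges a plain logistic fit is returned with a prominent
flag. Boundary (singular) fits — a variance component estimated at zero
— count as converged. Variance inflation factors are computed from the
fixed-effect design alone.

## Problem sizes, seeds and reproducibility

Every stochastic function takes an explicit seed, and `run_pipeline()`
derives per-stage seeds from one master seed, recording them with MD5
hashes of all outputs in a manifest; identical configurations reproduce
identical files. The package's own test and acceptance runs use
desk-scale versions of the design — cohorts of 4-8 observers, one block
per session, balanced 24-trial stimulus subsets, 250 Hz gaze — sizes
chosen so the full chain (including a 50-replicate sign-recovery study
for the mixed model and a 150-replicate calibration of the permutation
p) completes interactively while leaving every estimator in its
asymptotically sensible regime. `run_config(fast = FALSE)` restores the
full 15-observer, 3-block, 1000 Hz design.

## Known limitations

* The camera-FOV/screen-span calibration is under-determined by the
  scene description alone; `calibrate_fov()` exists precisely because
  the default cannot satisfy every printed span simultaneously.
* Pursuit gain remains a biased quantity whenever target motion is
  comparable to residual tracker noise; the NA guard and the MAD screen
  manage, but do not remove, this.
* The theoretical observer's noise placement (both intervals vs
  comparison only) is a convention, exposed as `noise_both`.
* Dominance analysis inherits the design's exact cue collinearity
  (start = 3 speed + end): full-model coefficients alias one cue, and
  dominance shares — not coefficients — are the interpretable output.
* The synthetic observer is a tool for validating estimators, not a
  model of human oculomotor control; its parameters should not be read
  as empirical claims.
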