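---
title: "Decoding interceptive saccade end-positions from synthetic parietal populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding interceptive saccade end-positions from synthetic parietal populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(saccpop)
```

## The question

Saccades to moving targets ("interceptive" saccades) land close to where
the target *is* at saccade end, not where it was when it appeared. The
oculomotor system must therefore extrapolate target motion across its own
sensorimotor delay. `saccpop` implements a population-decoding analysis of
this problem: train a decoder to read out saccade end-position from the
peri-saccadic activity of a population of spatially tuned neurons recorded
during saccades to *stationary* targets, then feed it the activity
recorded during *interceptive* saccades and ask how far the decoded
end-position lags behind the true one. If neurons encoded only a
"snapshot" of the target taken some fixed time before landing, the decoded
positions would be compressed toward the motion origin (the screen center)
by `speed * lag`; the lag recovered from that compression is the package's
central quantity.

Because the recordings that motivated this analysis are not publicly
deposited, the package ships a synthetic-cohort generator that plays the
role of the recorded data and turns every downstream claim into a
parameter-recovery statement: the generator plants a known snapshot offset
`tau` and the pipeline must read it back out.

## The generative model

A session contains regular trials (visually guided saccades to 17
stationary positions: the center plus 8 directions at 2 and 4 deg) and
interceptive trials (saccades to targets leaving the center at 10 deg/s in
8 directions). Trial kinematics follow the experimental scales: latency
134 +/- 44 ms, duration 36 +/- 8.9 ms (both clamped at +/-2 SD to stay
physical), endpoint scatter SD 0.8 deg (matching the residual SD of the
behavioral regression this design targets). Regular saccades land on the
target plus noise; interceptive saccades land on the *target position at
saccade end* plus the same noise, so the motion-aligned endpoint component
("intercept") grows with saccade end time at exactly the target speed —
the behavioral regression recovers `slope = target_speed` by construction,
and that closed form is the oracle for the corresponding tests.

Eye traces are synthesized at 1 kHz as fixation (default at (0, 9) deg,
eccentric enough that all saccade amplitudes exceed ~3 deg and trip the
100 deg/s detection criterion) + minimum-jerk saccade + post-saccadic
pursuit at target velocity (interceptive) or fixation (regular), plus
white positional noise (SD 0.05 deg). The trial-to-trial correlation
structure between latency, duration and endpoint scatter is not modeled;
they are independent draws.

Each neuron fires as an inhomogeneous Poisson process (sampled exactly, by
thinning) with rate

```
rate(t) = baseline + (peak - baseline) * (u * G_time(t) + G_space(eff) * G_time(t_eff)) / (1 + u)
```

where `G_space` is a unit-peak 2-D Gaussian over saccade end-position
(centers over +/-6 deg, SD 1.2-2.5 deg), `G_time` a unit-peak Gaussian
over peri-saccadic time (peaks N(0, 25 ms) clamped at +40 ms, SD
35-60 ms), and `u` the gain of a spatially *untuned* saccade-locked
component (U(0.3, 0.9)). Three of these choices deserve comment, because
they were made so that the population has the qualitative structure the
decoding analysis probes rather than an idealized one:

* **The untuned component.** Parietal saccade-related neurons respond to
  some degree at all end-positions, not only near their preferred one.
  Without this component the spatial pattern of a population response is
  equally informative in every time window (only its amplitude changes
  with `G_time`), which makes the sliding-window time course degenerate:
  decoding quality saturates, and the window-by-window bias curve has a
  flat, noise-dominated bottom. The untuned component dilutes the
  spatial information without removing the saccade-locked drive, giving
  decoding a genuine time course.
* **Tuning centers beyond the workspace (+/-6 deg for a +/-4 deg decoded
  area).** With centers confined to the workspace, the population's total
  firing falls off toward the edge, and total rate becomes a spatial cue;
  the decoder then misreads any condition-wide amplitude difference as an
  eccentricity change. Spreading centers past the workspace keeps total
  rate approximately flat over the tested region.
* **No purely post-saccadic temporal peaks.** Response timing is drawn as
  build-up/burst-like (clamp at +40 ms), so population information decays
  quickly after the saccade and the time course has a unique minimum.

The snapshot offset `tau` (ms, default -50) is the planted parameter. It
is referenced to **saccade end**: during interceptive trials the tuned
component responds as if the saccade had landed where the target was at
`t_end + tau`, i.e. its spatial argument is shifted against the motion
direction by `|tau| * speed / 1000` deg (endpoint scatter is preserved),
and its temporal profile is delayed by `|tau|` (the neuron represents the
target with a fixed processing lag in both position and time). `tau = 0`
is the exact identity: an interceptive and a regular trial landing at the
same point produce identical rates, which is what makes the regular
condition a clean control. Expected recoveries: decoded interceptive
positions biased toward the center by `|tau| * speed / 1000 = 0.5` deg,
and the sliding-window bias minimum delayed by `|tau|`.

Seeding is hierarchical (session seed, then per-trial, then
per-trial-per-neuron), so the behavioral record is bit-identical whether a
cohort has 5 or 105 neurons, and every analysis function takes an explicit
seed.

## Saccade detection and behavioral statistics

Eye traces are smoothed with a 15 ms moving average (window truncated at
the edges); 2-D speed is computed by central differences. Detection uses a
double velocity criterion: the first sample above 100 deg/s triggers a
saccade; the onset is the last preceding sample below 30 deg/s (backward
walk) and the offset the first subsequent sample below it. Only the first
saccade of a trial is analyzed, and a trace that never exceeds 100 deg/s
yields an explicit no-event result. Pre-/post-saccadic positions are
averaged 16-6 ms before onset and 2-4 ms after offset — the short
post-window avoids contamination by pursuit. On synthetic trials the
detector recovers ground-truth onsets/offsets to within ~3 ms; trials the
detector misses (a few percent at the smallest amplitudes, where the
minimum-jerk peak velocity approaches the criterion) are simply excluded,
as they would be in practice.

The intercept of an end-position `(x, y)` for motion direction `alpha` is
`x cos(alpha) + y sin(alpha)`. Its OLS regression on saccade end time
(slope in deg/s) carries a percentile bootstrap CI at p = 0.01 (2000
trial-level resamples, seeded). Endpoint clouds per direction are
summarized by sample mean and covariance (1-SD ellipse), with a singular
covariance flagged rather than fitted. The direction-selectivity inclusion
test is a two-sample t test (p < 0.01) on spike counts in the +/-100 ms
window; two constant count lists are excluded with a flag instead of
producing a t statistic.

## Tuning fields

Spike times aligned to the detected saccade onset are convolved with a
unit-area Gaussian (sigma = 20 ms, truncated at 4 sigma, < 1e-4 of the
mass) and averaged over trials to give a response function in spikes/s on
a -400..+350 ms grid (10 ms steps). Interpolation is staged: time first
(the response functions live on the time grid per anchor end-position),
then space per time slice — piecewise-linear interpolation on a Delaunay
triangulation of the anchor set (mean detected end-positions: 17 regular
anchors, 8 interceptive) over the -4..+4 deg grid in 0.1 deg steps
(81 x 81 x 76), with nearest-anchor extrapolation outside the convex hull
so activity is never overestimated where it was not sampled. The
triangulation is built by Bowyer-Watson insertion; because symmetric
layouts contain exactly cocircular quadruples (which make the incircle
predicate degenerate), a deterministic jitter of ~1e-7 of the point scale
is applied to the triangulation copies of the anchors — interpolation
weights change by a comparable, negligible amount, and the scheme is
verified to reproduce anchor values and linear functions.

## Similarity of regular and interceptive tuning

Window-averaged (+/-100 ms) spatial maps of the two conditions are
compared by Pearson correlation and by the similarity index

```
SI = 1 - ||z(R) - z(I)||_F / (||z(R)||_F + ||z(I)||_F)
```

restricted to the central 1.5 deg where both conditions are sampled. The
z-transform is not uniquely defined by the index's usual statement; this
package standardizes each map entrywise (subtract its mean, divide by its
SD), which makes SI symmetric, bounded in [0, 1], equal to 1 only for
identical z-maps, and invariant under positive affine rescaling of either
map. The cost of that choice is insensitivity to overall rate differences
between conditions; a `center_only` variant (subtract the mean, keep the
scale) is exposed for analyses where amplitude differences matter, and the
degenerate case (a constant map) is flagged rather than guessed at. Under
full standardization the index has the closed form
`SI = 1 - sqrt((1 - r) / 2)`, which makes the r > 0.5 / SI > 0.3 selection
thresholds (strict inequalities) nearly redundant on clean synthetic maps;
both are still applied as stated. Subpopulation selection is exercised in
the workflow but the headline decoding runs use the full cohort.

## Pseudo-populations and the decoder

For each of `n_splits` stratified 70/30 train/validation splits of the
regular trials (the interceptive trials are never used for training, so
they need no splitting), training maps are built from the training trials
only. A pseudo-trial draws a uniform end-position in the +/-4 deg square
and, per neuron, an independent Poisson count with mean `map(position) *
window_duration`. The decoder is the fixed shallow network n_neurons ->
20 -> 20 -> 2 (tanh hidden units, linear output) trained on mean squared
error with inputs standardized by training-set mean/SD. Training is
full-batch quasi-Newton (L-BFGS-B with analytic backprop gradients); a
Jacobian-based Levenberg-Marquardt step would need an
n_trials x n_weights Jacobian (~2600 weights), which is prohibitive at
these trial counts, and the relevant contract is validation error, not
the trainer. Under-converged decoders leave a radial bias at the tested
ring, so the default iteration budget is deliberately generous
(`maxit = 500` for the broad window).

Evaluation happens at the 8 tested positions — the mean interceptive
end-positions per direction (~1.7 deg eccentric), the only locations
where both conditions have data — using regular *validation* maps and
full-data interceptive maps. Per split and position the mean and SD of
the predictions, the nearest-position confusion matrix (ties to the
lowest index; "direct neighbors" are the two angularly adjacent ring
positions, so chance is 12.5% correct and 37.5% correct-or-neighbor), and
the center bias `intercept(tested) - intercept(predicted)` are recorded;
statistics are averaged across splits, never pooled across trials first.
Two derived quantities need care:

* **Anchor error.** Per-split mean predictions at an anchor scatter with
  the validation maps, which rest on only ~3 trials per anchor (endpoint
  scatter alone contributes ~0.8/sqrt(3) deg of anchor noise); the
  per-split error therefore overstates what the combined decoder knows.
  The summary error is the distance of the *across-split mean* prediction
  from the tested position; the mean per-split error is reported
  alongside.
* **Snapshot recovery.** Any finite-data decoder shrinks its predictions
  toward the training prior's center, in both conditions alike. The
  planted displacement `|tau| * speed` is therefore recovered as the
  interceptive-minus-regular center-bias difference, with the regular
  condition acting as the `tau`-free control; raw per-condition biases
  are reported too.

The prediction error field repeats the evaluation over a grid of
positions within 1.5 deg of the center: a compression toward the center
appears as error vectors (`tested - predicted`) aligned with the outward
radial direction — the "pinwheel" signature, quantified by the signed
radial component per node.

The sliding-window analysis retrains the decoder per 100 ms window
stepped by 50 ms across -400..+350 ms (14 windows) and per split, with a
reduced pseudo-trial budget (4000) and iteration budget (200) per window;
a paired t test across the 8 tested positions compares the conditions per
window at p < 0.01. Window averages are inclusive time-grid means, and a
window's expected count is its mean rate times its duration.

## Problem sizes and reproducibility

The study-scale conditions are 105 neurons, 50 splits and 100,000
pseudo-trials; they are the package defaults in `default_config()`. The
analysis scripts, tests and the acceptance script run a reduced profile —
5 splits, 20,000 pseudo-trials (4000 per sliding window), 150 evaluation
trials per position — chosen as the point where the recovered quantities
are stable to well within their acceptance tolerances while a complete
run stays comfortably interactive. Every random step (cohort, session,
splits, pseudo-trials, weight initialization, bootstrap) takes an explicit
seed, and `run_pipeline()` re-run with the same configuration reproduces
its statistic tables byte-identically.

## What passing tests do and do not show

The generator produces Poisson spiking with smooth Gaussian tuning,
independent neurons, stationary noise, and a single planted snapshot
mechanism. Real recordings have correlated variability, non-Poisson
dispersion, mixed and drifting tuning, session-to-session alignment error
and a heterogeneous (not single-valued) snapshot continuum. Parameter
recovery here therefore validates the *pipeline* — detection, field
construction, resampling, decoding and the bias statistics — not any
claim about biological populations; with real data the same code measures
rather than recovers. Known limitations: the behavioral generator treats
latency, duration and endpoint scatter as independent; the similarity
index's standardization discards amplitude differences by design; the
decoder's center-ward shrinkage is a property of regression decoders at
finite information and is handled by differencing against the control
condition rather than removed.
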