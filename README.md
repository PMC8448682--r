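# saccpop — population decoding of interceptive saccade end-positions

Saccades to moving targets land close to where the target *is* at saccade
end, which means the oculomotor system extrapolates target motion across
its sensorimotor delays. Whether a given neural population carries the
information needed for that extrapolation can be asked with a decoding
experiment: train a model to read out saccade end-position from
peri-saccadic population activity recorded during saccades to *stationary*
targets, feed it the activity recorded during *interceptive* saccades, and
measure how far the decoded end-positions lag behind the true ones.
`saccpop` implements that entire analysis for R users — and, because the
motivating recordings are not publicly deposited, it ships a synthetic
cohort generator with a planted "snapshot" offset so every statistic can
be validated by parameter recovery.

The pipeline, in the field's standard notation:

* **Behavior.** Saccades are detected from 1 kHz eye traces (15 ms moving
  average; double velocity criterion, 100 °/s trigger and 30 °/s bounds).
  The motion-aligned component of an end-position is the *intercept*
  `x·cos(α) + y·sin(α)` for motion direction `α`; its regression on
  saccade end time has slope equal to the target speed if interception is
  perfect. End-point clouds are summarized by fitted 2-D Gaussians.
* **Tuning fields.** Spike times aligned to saccade onset are convolved
  with a Gaussian (σ = 20 ms), averaged over trials, and interpolated
  over saccade end-position (linear on the triangulated anchor set,
  nearest-neighbor outside it) onto an 81 × 81 × 76 grid
  (±4° in 0.1° steps, −400…+350 ms in 10 ms steps).
* **Similarity.** Regular vs interceptive maps are compared by Pearson r
  and the similarity index
  `SI = 1 − ‖z(R) − z(I)‖_F / (‖z(R)‖_F + ‖z(I)‖_F)`;
  neurons with r > 0.5 and SI > 0.3 form the "most similar" subpopulation.
* **Decoding.** For each stratified 70/30 split, Poisson pseudo-trials are
  drawn from the training maps (`counts ~ Poisson(rate · window)` at
  uniform end-positions), and a shallow network (n_neurons → 20 → 20 → 2,
  tanh hidden units, MSE loss, quasi-Newton training) decodes (x, y).
  Evaluation at the 8 mean interceptive end-positions yields confusion
  matrices (chance: 12.5 % correct, 37.5 % correct-or-neighbor), the
  *center bias* `intercept(tested) − intercept(predicted)`, prediction
  error fields, and sliding-window (100 ms / 50 ms steps) time courses.
  A center bias `b` at target speed `v` converts to a time lag
  `1000·b/v` ms on the target.

## Worked example

The `analysis/` scripts run the full workflow as numbered stages over one
synthetic session (105 neurons with a −50 ms snapshot offset, 10 trials ×
17 stationary positions, 15 trials × 8 motion directions at 10 °/s):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_behavior.R
Rscript analysis/03_tuning.R
Rscript analysis/04_decode.R
Rscript analysis/05_sliding.R
```

which prints (tables go to `results/`):

```
simulated 290 trials (170 regular, 120 interceptive), 105 neurons
mean ground-truth latency 135 ms, duration 36 ms
detected 290 / 290 saccades
mean interceptive deflection 1.84 deg
intercept vs end time: slope 9.42 deg/s (99% CI 8.71..10.10), offset 0.133 deg, r = 0.444
similarity over 105 neurons: median r = 0.35, median SI = 0.43
42 neurons pass r > 0.5 and SI > 0.3
regular:      anchor error 0.34 deg, bias 0.20 deg, 49% correct, 91% correct-or-neighbor
interceptive: bias 0.65 deg, 39% correct, 80% correct-or-neighbor
snapshot displacement 0.45 deg = 45 ms of target motion
error field: 8 of 8 eccentric nodes centripetal; center magnitude 0.07 deg
tau = -50 ms: bias minima regular 0 ms, interceptive 50 ms; 3 significant windows
tau = 0 ms: bias minima regular 0 ms, interceptive 0 ms; 0 significant windows
```

Reading the decoding block: regular-saccade end-positions are recovered to
0.34° on average and interceptive predictions are compressed toward the
screen center (the pinwheel error field). The interceptive-minus-regular
center-bias difference, 0.45°, converts at 10 °/s to ~45 ms of target
motion — recovering, to within its sampling error, the −50 ms snapshot
offset planted in the generator. The sliding-window stage shows the
temporal signature of that same lag — the interceptive bias minimum
trails the regular minimum by one 50 ms step, and the effect vanishes in
the τ = 0 control cohort.

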