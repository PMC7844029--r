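---
title: "Identifying head- and eye-movement coding with LN Poisson encoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying head- and eye-movement coding with LN Poisson encoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnspike)
```

## The problem

Neurons in the medial entorhinal cortex (MEC) fire as a function of many
behavioral variables at once: body position and speed, azimuth head
direction, head pitch and roll, angular head velocity, and — in head-fixed
preparations — the position and velocity of the eyes. Because these
variables are correlated in natural behavior (a mouse turning its head is
usually also moving), asking whether a neuron "encodes pitch" by simply
correlating firing with pitch invites false positives. `lnspike`
implements the model-comparison approach that addresses this: a
linear-nonlinear (LN) Poisson encoding model with spline-basis inputs,
cross-validated forward variable selection, and model-derived tuning
curves in which the contribution of every other encoded variable is
averaged out.

## The model

Spike counts `n_t` in 20 ms bins are modeled as Poisson with expected
count

    lambda_t = exp( b0 + sum_i X_i(t) . w_i )

where `i` indexes behavioral variables, `X_i(t)` is the *animal-state
vector*: a cardinal-spline basis encoding of variable `i`'s value at time
`t`, and `w_i` are learned weights on the variable's spline control
points. The firing rate in spikes/s is `lambda_t / dt` with `dt = 0.02 s`.

Each variable is binned into control points (open field:
`round(arena_cm * 15/100)` position bins per axis, 10 azimuth bins,
5 cm/s speed bins, 8 bins for pitch, roll and azimuthal head velocity;
virtual track: 20 circular position bins, 5 cm/s speed bins, 5 bins per
eye variable). A value `y` between control points `z_j` and `z_{j+1}`
activates points `j-1..j+2` with weights
`[a^3 a^2 a 1] %*% M(s)`, `a = (y - z_j)/(z_{j+1} - z_j)`, where `M(s)`
is the 4x4 cardinal blending matrix with tension `s`. Every weight row
sums to one (partition of unity), so a constant weight vector contributes
a constant rate — the model cannot manufacture structure from the basis
alone. We default to `s = 0.6`, the middle of the 0.5–0.7 band within
which results are insensitive to the tension.

Two boundary conventions matter and are tested:

* circular variables (azimuth; virtual-track position) wrap control-point
  indices modulo the bin count, so a value at 359.9 degrees activates
  points on both sides of the 0-degree seam;
* non-circular variables eliminate the two phantom points beyond the grid
  by linear extension (`w_0 = 2 w_1 - w_2`), which preserves the
  partition of unity and keeps every index inside `1..W`.

### Fitting

Parameters maximize the penalized Poisson log-likelihood
`sum_t [ n_t log lambda_t - lambda_t ] - beta * sum_i ||w_i||^2` with
`beta = 1` and the offset `b0` unpenalized (penalizing the offset would
bias the mean rate). The objective is concave; we use a damped Newton
iteration with the analytic gradient and Hessian, run in compiled code on
a compressed-sparse-row view of the design (at most 4 active control
points per variable per time bin, 16 for 2-D position). Convergence is
declared at gradient sup-norm `1e-6`; fold fits are warm-started from the
full-data fit and candidate models from the current selected model. A
unit test cross-checks the solver against an independent ridge-Poisson
implementation (`glmnet`) on a small problem.

### Data preprocessing

Model input is restricted to time bins where *every* candidate variable
lies inside its percentile inclusion window — 2.5–97.5% for freely moving
(open-field) sessions, 1–99% for head-fixed sessions — and is unmasked.
Windows are computed per variable on the full session, independently of
the other variables (the joint retained set is their intersection).
Restricting to the candidate-joint mask keeps fold-wise log-likelihoods
comparable across nested models during selection. Circular variables have
no percentile window (a percentile of an angle is not well defined).

### Cross-validation and forward selection

Performance is the *log-likelihood increase* (LLI) of a model over the
training-set mean-rate model on held-out data, computed by 10-fold
cross-validation. Folds are contiguous 10-s sections of the retained time
axis allocated round-robin to the 10 folds, so no two folds overlap and
each is temporally balanced; the spike-normalized variant divides by the
held-out spike count (reported in bits/spike).

Selection is a heuristic forward search: fit all single-variable models
and keep the best by mean LLI; repeatedly try to add the best-scoring
additional variable, accepting it if a one-sided Wilcoxon signed-rank
test on the 10 fold-paired LLIs rejects at `alpha = 0.05`; finally,
require the selected model to beat the mean-rate baseline with the same
test, otherwise the cell is classified as encoding nothing. Ties in mean
LLI break lexicographically by variable symbol (documented, rarely
exercised).

### Model-derived tuning curves

The tuning curve of variable `i` is

    C_i(m) = exp( Y_i(m) . w_i ) * gamma / dt ,   m = 1..200

where `Y_i(m)` is the state vector at the m-th bin center and
`gamma = exp(b0) * prod_{v != i} mean_t exp(X_v(t) . w_v)` is the average
rate contribution of every other encoded variable. For a single-variable
model the product is empty and `gamma = exp(b0)`. The occupancy-weighted
mean of the curve reproduces the cell's mean firing rate (tested within
5%). Fold-wise curves from the 10 cross-validation fits give the
dispersion (sem) shown by `plot()`. Raw tuning curves (spikes divided by
occupancy seconds in 20 bins, robust-lowess smoothed over 7 bins) agree
with the model-derived curves on simulated data with r > 0.9.

Curves are displayed over the behavioral percentile range intersected
with preset bounds (±50 deg for pitch/roll, ±100 deg/s for azimuthal head
velocity, ±3 and ±2 % eye width for horizontal and vertical eye
variables).

### Shape classification

Curves are range-normalized to [0, 1] (pitch/roll curves additionally
Gaussian-smoothed over a 20-bin window) and fit by polynomials of degree
1–5; the accepted degree is the lowest whose *fraction of error
explained*, `1 - MSE(poly)/MSE(flat mean)`, reaches 0.9. Classification
is attempted only when the curve covers at least 50% (head variables) or
80% (eye variables) of the preset range; flat curves (baseline MSE below
`1e-12`) are reported as undefined rather than guessed. Eye curves are
not smoothed before classification; only pitch and roll are.

Velocity curves are subclassified from the least-squares slopes fitted on
either side of zero velocity: degree-1 curves are linear-asymmetric
(`L_as`); curves whose side slopes have opposite signs with a magnitude
ratio of at least 0.5 are nonlinear-symmetric (`NL_s-pos` V-shaped,
`NL_s-neg` inverse-V); the rest are nonlinear-asymmetric (`NL_as`),
preferring the larger-|slope| side. The 0.5 symmetry threshold is a
package choice (no numeric criterion exists for it in the literature we
follow) and is exposed as an argument. Peak/valley locations come from
`pracma::findpeaks` on the curve and its negative, taking the global
extremum.

### Stability and contributions

Tuning stability refits the cell's full selected model separately on each
half of the session and correlates the two curves over the intersection
of their behavioral ranges, up-sampling the shorter curve by linear
interpolation (the interpolation method is our choice; only "up-sampled"
is prescribed). The unique contribution of a variable is the drop in
spike-normalized held-out LLI when the variable is removed and the
reduced model refit on the same folds. We report this raw difference as
primary, and also provide the normalized variant
(`1 - LLI_reduced/LLI_selected`) and a correlation-based analogue; the
raw difference is the form in which such contributions are usually
plotted, and the normalized variant is kept because both conventions
circulate.

## Population statistics

* **Direction preference**: `binomial_preference_test(k, n)` reports the
  continuity-corrected normal statistic
  `z = sign(k - n/2)(|k - n/2| - 0.5)/(sqrt(n)/2)` together with the
  exact two-sided binomial p (doubled smaller tail, capped at 1). This
  joint convention reproduces the published worked examples it is tested
  against (e.g. 26/44 -> Z = 1.06, P = 0.29) and is the only supported
  one.
* **Entropy and mutual information** use empirical bin probabilities and
  the natural logarithm (nats); the MI shuffle null permutes one
  variable.
* **Tuning-space clustering**: curves are row-centered, scaled to unit
  range, projected on the first two principal components; the mean
  distance of labeled cells to their k nearest same-label neighbors
  (k = 1..10) is compared with a label-permutation null (default 1000
  permutations), significant at the Bonferroni bar 0.05/10. Calibration
  under random labels is property-tested (p approximately uniform).

## Validation controls

* **False-detection rate**: permuting one variable's values over time
  destroys its relationship to spiking while preserving its marginal
  exactly; re-running the full selection estimates how often the
  shuffled variable is falsely selected (design level alpha = 0.05).
* **Ablated regeneration**: spike trains regenerated from a fit with the
  eye-variable blocks deleted should not re-select eye variables above
  the false-detection rate; this is the control for eye-position/track
  correlations masquerading as eye coding.
* **Shuffle significance**: the classical alternative scores each cell by
  the Pearson correlation between a variable and firing rate against 500
  circular time-shifts of the spike train (shift > 20 s; wrapping
  preserves both the marginal and the autocorrelation — edge handling is
  unstated in the methods we follow, and circular shift is our choice).
  The null is computed for all shifts simultaneously by FFT circular
  cross-correlation of the masked variable series with the rate (and its
  square), which is exact — a unit test checks bit-level agreement with
  the per-shift loop — and makes 500-shuffle nulls essentially free.
  Within-cell and pooled nulls are both provided, with the two-sided
  2.5/97.5 rule, plus the symmetric-velocity variant (side correlations
  against 5/95 bounds) that rescues V-shaped cells the linear rule
  misses.

## The synthetic-data generator

Real recordings are not required anywhere: seeded generators produce (a)
open-field foraging behavior — reflected-random-walk position,
circular-random-walk azimuth, mean-reverting (discretized
Ornstein-Uhlenbeck) pitch and roll; (b) head-fixed virtual-track running
with saccade-like heavy-tailed eye traces; (c) raw 3-axis accelerometer
streams for commanded head orientations (gravity-only; the exact inverse
of the pitch/roll recovery, including the head-fixed calibration
segment); (d) grayscale eye-camera frames with a dark pupil disk and
bright corneal reflection; and (e) Poisson spike trains from known LN
ground truth.

Process parameters are calibrated once to the published across-mouse
percentiles of the behavioral marginals: pitch OU(mean 11.5, sd 20 deg),
roll OU(mean -0.8, sd 26 deg), both with ~0.6 s time constants and an
exact affine match of the sample moments after light smoothing; azimuthal
velocity is a two-state (slow/fast) Markov regime switch over a
unit-variance AR(1), giving the Gaussian scale-mixture marginal
`0.85 N(0, 45^2) + 0.15 N(0, 400^2)` (deg/s) whose quartiles and 2.5/97.5
percentiles land inside the published mean ± 3 sem envelopes. Eye traces
are a slow OU base (time constants 6–8 s) plus exponentially decaying
jump pulses at ~0.4–0.5 events/s with asymmetric exponential amplitudes;
the sample median is anchored to the published median (the generator's
calibration contract), and the position and smoothed-velocity percentiles
fall inside the published envelopes for all four eye channels.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: vestibulo-ocular head-eye coupling, true
saccade kinematics (main-sequence velocity profiles), video compression
artifacts, non-Poisson spiking (bursting, refractoriness), slow rate
drift, and the joint dependence structure between behavioral variables
beyond what the marginal calibration induces. Only marginals are matched;
published joint statistics are not reproduced.

## Numerical choices and scales

* Time bins are half-open `[t, t + dt)` with `dt = 20 ms` fixed; a spike
  at exactly a bin edge belongs to the later bin.
* The azimuth convention is `atan2` counterclockwise from +x, mapped to
  `[0, 360)`; angular differences take the shortest signed arc, so
  `|dH_a| * dt <= 180 deg` always.
* Sign conventions (our choice, applied consistently and documented in
  `compute_pitch_roll`): pitch positive = head up; roll positive =
  rightward (ipsiversive for right-hemisphere recordings). The unsigned
  arccos of the projection angle is signed by the in-plane coordinate.
  Directional results are therefore convention-relative.
* Pupil frames: bad frames (connected-pixel count outside the open
  interval (50, 1000)) are linearly interpolated; drift is removed with a
  1000-point Gaussian (sigma = window/6, only the window length being
  prescribed); the top/bottom 1% of values per coordinate are masked
  *after* high-pass filtering, following the order of operations in the
  protocol text; the circle fit is algebraic least squares (Kasa);
  sessions with more than 25% invalid frames are rejected (our
  threshold).
* Default simulation scales used by the tests and the acceptance script:
  20-min sessions at 50 Hz (60,000 bins) for model-recovery experiments,
  10-min sessions for null calibration, 50 ground-truth cells for the
  selection-recovery measurement, 500 shuffles for significance nulls,
  1000 permutations for the clustering test. These sizes make every
  stochastic criterion measurable with binomial confidence while keeping
  a full run on one CPU within minutes.

## Known limitations

* The 2-D position spline uses a tensor-product basis; very small arenas
  (< 27 cm) fall back to the 4-control-point minimum per axis.
* Percentile windows are estimated per variable on the whole session;
  with strong nonstationarity the retained mask can differ between
  session halves, which the stability analysis handles by intersecting
  behavioral ranges.
* The forward search is greedy: with strongly redundant variables it
  selects a sufficient, not necessarily unique, set — the same property
  the original procedure has.
* Reported LLI units are nats (raw) and bits/spike (normalized); other
  implementations may normalize differently, so compare shapes and
  signs, not absolute LLI magnitudes, across codebases.

## A worked example

```{r example, eval = FALSE}
library(lnspike)

# a 10-min head-fixed session and a conjunctive position x eye cell
ses <- simulate_vr_behavior(behavior_spec("vr_track", 600, seed = 1))
cell <- ground_truth_cell(log(0.1), list(
  B = tuning_place1d(150, 35, amp = 2),
  E_h = tuning_poly(c(0.9, 0), c(-3, 3))))
spikes <- generate_ln_spikes(cell, ses, seed = 2)

sel <- forward_select(ses, spikes)
print(sel)
summary(sel)

tc <- model_tuning_curve(sel$fit, "E_h", cv = sel$cv)
plot(tc)
classify_shape(tc)
tuning_stability(ses, spikes, sel$selected, "E_h")
variable_contribution(sel, "E_h")$contribution
```
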