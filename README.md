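# lnspike

Linear-nonlinear (LN) Poisson encoding models for identifying which
behavioral variables a neuron encodes — built for the self-motion
repertoire of medial entorhinal cortex (MEC): body position and speed,
azimuth head direction, head pitch and roll, angular head velocity, and
eye position/velocity in head-fixed virtual-reality sessions.

## Who this is for

Systems neuroscientists with synchronized behavior (50 Hz) and spike
trains (20 ms bins) who want a statistically defensible answer to "does
this cell encode pitch / eye position / azimuthal head velocity, over and
above the variables it already encodes?" — plus the upstream plumbing
(IMU-based pitch/roll derivation, LED tracking variables, pupil
tracking) and the downstream characterization (tuning-curve shape and
velocity-subtype classification, stability, population tests). Every
stage is testable without any recording: seeded generators produce
behavior, raw sensor streams and ground-truth spike trains.

## The model

Spike counts per 20 ms bin are Poisson with

    lambda_t = exp( b0 + sum_i X_i(t) . w_i ),      rate_t = lambda_t / dt

where `X_i(t)` is a cardinal-spline basis encoding (tension s = 0.6,
partition of unity) of behavioral variable `i` at time `t`. Fitting
maximizes the Poisson log-likelihood with an L2 penalty (beta = 1, offset
unpenalized) by damped Newton iteration in compiled code. Model
comparison uses the held-out log-likelihood increase (LLI) over a
mean-rate model, 10-fold cross-validated over 10-s sections; variables
are selected by a forward search gated by one-sided Wilcoxon signed-rank
tests on fold-paired LLIs (alpha = 0.05), with a final test against the
mean-rate baseline. Tuning curves with other variables' contributions
averaged out are

    C_i(m) = exp( Y_i(m) . w_i ) * gamma / dt,
    gamma  = exp(b0) * prod_{v != i} mean_t exp( X_v(t) . w_v ).

See the vignette (`vignettes/ln-encoding-models.Rmd`) for the full
methods account: preprocessing windows, fold construction, shape and
velocity-subtype classification, population statistics, shuffle-based
controls, and the synthetic-data calibration.

## A worked example

```r
library(lnspike)

# a 10-min head-fixed virtual-track session and a conjunctive cell that
# encodes track position and horizontal eye position
ses    <- simulate_vr_behavior(behavior_spec("vr_track", 600, seed = 1))
cell   <- ground_truth_cell(log(0.1), list(
            B   = tuning_place1d(150, 35, amp = 2),
            E_h = tuning_poly(c(0.9, 0), c(-3, 3))))
spikes <- generate_ln_spikes(cell, ses, seed = 2)

sel <- forward_select(ses, spikes)
print(sel)
#> Forward selection of LN model variables
#>   selected: B + E_h
#>   mean held-out LLI: 208.08 nats (0.501 bits/spike)
#>   final vs mean-rate baseline: p = 0.000977
summary(sel)
#> Selection path:
#>  step best mean_lli            p
#>     1    B 177.3247           NA
#>     2  E_h 208.0808 0.0009765625
#>     3 dE_v 207.8892 0.6875000000
```

The search finds track position first (mean held-out LLI 177.3 nats),
adds horizontal eye position (208.1 nats, signed-rank p < 0.001), and
stops when the best third variable fails the test (p = 0.69) — exactly
the generative model. Characterizing the recovered eye tuning:

```r
tc <- model_tuning_curve(sel$fit, "E_h", cv = sel$cv)
print(tc)
#> <tuning_curve> E_h (model), 200 bins on [-3, 3], rate 4.64-21.12 spikes/s
classify_shape(tc)
#> degree-1 tuning (fraction of error explained 0.972); peak at 2.98
tuning_stability(ses, spikes, sel$selected, "E_h")
#> [1] 0.976
variable_contribution(sel, "E_h")$contribution
#> [1] 0.0743
```

The cell is classified as linearly tuned to horizontal eye position
(97% of curve error explained by a line, peak at the nasal end), its
tuning is stable across session halves (r = 0.98), and removing `E_h`
costs 0.074 bits/spike of held-out prediction. Population-level direction
preferences use the continuity-corrected binomial test:

```r
binomial_preference_test(26, 44)
#> binomial preference test: 26/44, Z = 1.06, P = 0.291
```

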