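---
title: "Methods: corticospinal excitability and stability analysis for destabilised gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corticospinal excitability and stability analysis for destabilised gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmep)
```

## Overview

`gaitmep` implements an analysis chain for studies that probe corticospinal
excitability with transcranial magnetic stimulation (TMS) while participants
walk on a treadmill, comparing steady-state gait with gait destabilised by
continuous pseudorandom mediolateral platform oscillations. The chain runs
from raw-like inputs (marker trajectories at 100 Hz, EMG at 2000 Hz,
stimulation times, the platform displacement signal) to group-level
statistics:

1. **Gait events** — heel strikes at the vertical heel-marker minimum,
   toe-offs at its largest upward acceleration; step width, stride duration
   and their variances.
2. **Local dynamic stability** — the local divergence exponent `lambda_s`
   from the mediolateral thorax velocity, via Rosenstein's algorithm.
3. **Foot-placement control** — the linear regression of mediolateral foot
   placement on the pelvis (CoM-proxy) position and velocity over the
   single-leg-stance phase; `R^2`, its Fisher transform, and the
   foot-placement error.
4. **MEP extraction** — zero-phase 20–500 Hz band-pass, ongoing EMG in the
   −20..+10 ms window with the artifact sample removed, absolute MEP as the
   10–60 ms peak-to-peak, MEP gain as their ratio; coil-displacement
   exclusions.
5. **Cyclic smoothing** — von Mises (circular) kernel regression of the
   sparse per-stimulation outcomes onto a 0.5 % gait-cycle grid, with
   kernel-density weights.
6. **Cyclic cluster-based permutation tests** between conditions, wrapping
   clusters across the cycle boundary.

A synthetic-session generator with full ground truth stands in for raw
recordings; every stage of the analysis is validated against quantities the
generator knows exactly.

## The synthetic generator: what it emulates

`session_config()` fixes the study conditions. Defaults mirror the protocol
the package targets: 20-min trials, 4.0 km/h belt speed, 100 mm
peak-to-peak platform oscillation in the destabilised condition (zero in
steady state), stimulations scheduled at a right heel strike plus a uniform
random delay with 3–5 strides between pulses, seven right-leg muscles.

**Platform oscillation.** The protocol only requires a band-limited
pseudorandom signal; we use a sum of 12 sinusoids with randomly drawn
(hence mutually incommensurate) frequencies in 0.1–1.0 Hz, exactly rescaled
so max − min equals the configured peak-to-peak. Any other band-limited
choice would serve; the analysis never assumes a spectrum.

**Heel kinematics.** Each leg's vertical heel trajectory follows a smooth
periodic template: a 3 mm Gaussian contact notch whose minimum falls
exactly on the (sample-aligned) heel strike, plus a 60 mm swing bump whose
*acceleration* profile is designed directly — a sharp symmetric peak just
after heel-off, a broad deceleration lobe around swing apex, and a smaller
landing lobe, with two amplitudes solved so the profile integrates back to
zero height and velocity. Designing the acceleration rather than the
position has two virtues: the detector's target (the acceleration maximum,
i.e. toe-off) is a symmetric peak that zero-phase low-pass filtering does
not displace, and the stored ground-truth toe-off is the analytic argmax of
the template. Stride durations are drawn per stride (truncated normal) and
event times are snapped to the marker sample grid, so noise-free detection
can be exact.

**Foot placement.** The pelvis (mean of the two posterior superior iliac
spine markers) moves with phase-locked sway, a configurable coupling to the
platform displacement, and low-frequency noise. At each heel strike the new
heel position obeys the linear CoM-feedback law

```
FP = sgn * W + beta_pos * (PELpos - c_pos) + beta_vel * (PELvel - c_vel) + eps
```

in exactly the frame the analysis uses: position relative to the stance
heel marker at the contralateral toe-off instant, velocity relative to the
moving support surface. The centring constants are nominal (half the step
width; the phase-locked sway velocity at contact, which keeps the mean step
width at its configured value). Because the analysis demeans predictors and
outcome empirically, coefficient recovery is invariant to this choice — with
`epsilon_sd = 0` the fitted coefficients equal the configured ones to
machine precision, which the tests assert. `step_width_sd` is folded into
the placement residual alongside `epsilon_sd`: it models placement
variability not attributable to CoM feedback.

**EMG and MEPs.** Each muscle is envelope-modulated band-limited noise; the
noise is normalised to unit mean rectified value so the envelope *is* the
expected ongoing EMG in microvolts. At each stimulation a damped-sinusoid
MEP (125 Hz carrier, 15 ms decay, 15 ms onset — the waveform is a free
choice; only the 10–60 ms window matters downstream) is injected with
peak-to-peak amplitude `gain(cycle%) * envelope(cycle%)` times
multiplicative noise, plus a single-sample stimulation artifact. A
condition effect is injected as a multiplicative gain factor over a
configurable cyclic window, which makes the power of the cluster test
tunable. Coil displacements are drawn with a controlled threshold
exceedance rate.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: soft-tissue marker artifacts, marker dropout,
non-stationary fatigue drifts, EMG cross-talk, true musculoskeletal
dynamics, and ground-reaction forces. The generator's value is that the
statistical structure the analysis *assumes* (periodic kinematics, a linear
placement law, amplitude-modulated EMG, cyclic excitability profiles) is
present with known parameters, so estimator bias and calibration can be
measured.

## Event detection

Heel strikes are local minima of the vertical heel coordinate; toe-offs are
maxima of its second derivative after a 10 Hz zero-phase low-pass (the
protocol specifies neither a separation rule nor a differentiation scheme,
so these are package choices). Three safeguards matter in practice:

- a minimum separation of half the stride period (estimated from the
  autocorrelation) between accepted events, value-ordered so the deepest
  minimum / strongest peak wins;
- an amplitude criterion — only minima in the lowest part of the range
  (rejecting shallow noise minima on the flat stance plateau) and only
  acceleration peaks comparable to the per-cycle maximum;
- a mask around each heel strike when searching for toe-offs, because
  ground contact itself produces an acceleration transient that is not a
  toe-off. A corollary is that for a pure sinusoid — where acceleration
  maxima coincide with the minima — the detector deliberately reports the
  strongest peaks *outside* the contact neighbourhood; the sinusoid is a
  useful oracle for heel strikes only.

Event times are reported at sample resolution, without sub-sample
interpolation. "Variance" in the spatiotemporal summary is the sample
variance with an `n − 1` denominator.

## Local divergence exponent

The state space is the time-normalised mediolateral thorax velocity
(average of C7 and both acromions) with five delayed copies. The embedding
delay (10 samples of a 100-sample stride) and the Theiler exclusion window
(half a stride) are conventions from the gait-stability literature; the
protocol fixes only the five copies and the 0–0.5-stride fitting window.
Neighbour search is Euclidean with ties broken by the earliest index;
numerically zero distances (recurrences of an identical state on a perfect
limit cycle) are excluded with a relative tolerance, otherwise the curve
would be dominated by `log(0)` artifacts. `lambda_s` is the least-squares
slope of the mean log-divergence curve over 0–0.5 strides.

Three oracles validate the estimator: a noiseless limit cycle gives
`|lambda_s| < 0.05`; the logistic map `x <- 4x(1-x)` with scalar embedding
gives an early divergence slope within 10 % of its known Lyapunov exponent
`ln 2`; and added observation noise increases `lambda_s` monotonically.

## Foot-placement model

For every step (contralateral toe-off to heel strike) the pelvis state is
resampled onto a 51-point phase grid (the protocol does not state a
resolution; 51 points at ~2 % of the step is finer than the smoothness of
the curves involved). Predictors and outcome are demeaned *within side*
before pooling left and right steps: the pelvis sits on opposite sides of
the stance foot for the two step types, an offset the common placement law
does not model. OLS is fitted per phase point without an intercept
(demeaning absorbs it). When no displacement signal is supplied the
velocity is the plain derivative; with one, the surface velocity is
subtracted, expressing the pelvis velocity relative to the support surface
(equivalent to "adding the treadmill's lateral velocity" under the opposite
sign convention for the displacement signal).

The Fisher transform is applied as `atanh(sqrt(R^2))` — the z-transform of
the multiple correlation R. Method descriptions in this literature vary
between "Fisher-transformed R" and "applied to R^2"; since `atanh` needs an
argument below one and both readings are monotonically related, cluster
inference is unaffected by the choice. Values are clipped at `1 - 1e-12`
to keep the transform finite. The foot-placement error is the SD of the
residual at the final phase point (the placement instant).

## MEP extraction

The "second-order bi-directional" Butterworth filter is read as a
second-order design applied forward and backward (zero phase, effective
fourth-order magnitude). Window endpoints are inclusive, with ms-to-sample
conversion by rounding; at 2000 Hz the ongoing-EMG window holds 61 samples
minus the artifact sample. A zero ongoing EMG yields a *missing* gain (the
record is retained, the gain excluded from smoothing) rather than an
infinity. Coil displacement is computed by predicting a calibrated virtual
marker from two independent rigid marker sets (helmet and head) via
least-squares rigid transforms (Kabsch); exclusion uses strict
inequalities — vertical > 5 mm or horizontal (Euclidean norm of the two
horizontal components) > 10 mm — and a participant-condition is flagged when
fewer than 100 stimulations survive.

## Cyclic smoothing

Sparse per-stimulation outcomes are regressed onto a 0.5 % cyclic grid with
a von Mises kernel (Nadaraya–Watson): the smoothed value is the
weight-normalised convolution, and the denominator — the kernel density — is
kept as the reliability weight. The concentration follows the large-kappa
Gaussian equivalence `kappa = 1 / sigma_rad^2`; a Gaussian sigma of 2 % of
the cycle gives 63.3, conventionally rounded to 60. The kernel is evaluated
directly at grid points, mathematically identical to convolving a binned
signal at this resolution, and uses the exponentially scaled Bessel
function so large concentrations cannot overflow.

A grid point is *valid* when at least six samples lie within a circular
distance of two kernel SDs (with ~2 samples per 1 % of cycle, a ±4 % arc
holds ~16 samples, so the rule only flags genuinely sparse regions; reading
"within 2 SD" as ±1 SD would contradict that arithmetic). Invalid points
are retained with their flag; they are not interpolated.

Group averaging is either unweighted (plain mean across participants) or
weighted by the normalised per-participant kernel densities, in which case
participants with more stimulations near a phase point dominate there.

## Cluster-based permutation testing

Pointwise paired t-statistics (classical, or weighted with
reliability-weighted variance `s2_w = sum w (d - dbar_w)^2 / (1 - sum w^2)`
and standard error `sqrt(s2_w * sum w^2)`, which reduces exactly to the
classical statistic at equal weights) are thresholded at the two-sided
Student critical value at alpha = 0.05 with `n − 1` degrees of freedom.
Maximal runs of same-sign significant points form clusters; runs touching
both ends of the grid with the same sign merge into one wrapped cluster,
respecting the cyclic phase axis. Cluster mass is the summed t.

The permutation scheme exchanges the two condition labels within each
participant (the sign-flip null of a paired design), with patterns drawn
with replacement from all `2^n`. Because the kernel smoother is linear and
operates per participant-condition, permuting stimulation-level data and
re-smoothing is *identical* to swapping the two pre-smoothed curves — the
implementation exploits this, smoothing once and flipping curves, and a
test asserts the equality of the two routes. The null statistic is the
maximum absolute cluster mass per permutation (the max-statistic convention
that controls the family-wise error across clusters and signs); a cluster's
p-value is the fraction of null values at or above its absolute mass,
floored at `1/n_permutations` (0.001 at the protocol's 1000 permutations),
and significance requires exceeding the 95th percentile of the null.
Zero-variance grid points are capped at a large finite t with a flag rather
than propagating infinities; ties at the critical value are not
significant.

Calibration is asserted empirically: on 200 null synthetic group datasets
(15 participants, 200 stimulations per condition, 500 permutations) the
family-wise false-positive rate must fall in [0.02, 0.09] at alpha = 0.05,
and detection power must be monotone over injected multiplicative effects
of 1.02, 1.05 and 1.12 — chosen to span low to high power so the gradient
is informative.

## Problem sizes used in the tests

The validation suite scales the study down so the whole chain stays
exercised: 60–120 s trials (≈ 55–110 strides) instead of 20 min, 2–6
participants in pipeline tests, 120–1000 permutations depending on what a
test asserts, and 20 seeds for the paired condition-contrast and
coefficient-recovery checks. These sizes are the package's choice of a
minimal configuration in which every estimator is identifiable and the
statistical assertions have adequate resolution; all protocol constants
(rates, windows, thresholds, kernel width, permutation floor) are the
full-scale ones.

## Known limitations

- The generator's placement law acts at the contact instant; mid-swing
  `beta(t)` curves on synthetic data reflect the interpolated heel
  trajectory, so only final-phase coefficients are compared to truth.
- The embedding delay and Theiler window for `lambda_s` are conventions;
  sensitivity to them is not explored automatically.
- Invalid (low-density) grid points are flagged but not interpolated; a
  participant-condition with wide empty phase regions should be excluded by
  the stimulation-count rule before this matters.
- The weighted t-statistic uses a reliability-weighted variance with
  `n − 1` degrees of freedom; this is an approximation (the effective
  degrees of freedom of a weighted mean are smaller), mitigated by the
  permutation calibration, which does not rely on the t reference
  distribution.
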