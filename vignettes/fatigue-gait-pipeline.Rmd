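---
title: "Methods: fatigue detection from equine gait IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fatigue detection from equine gait IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science behind
`equifatigue`: the models and procedures, the parameters that matter, what
the synthetic data does and does not emulate, and the choices we made where
the design was genuinely open.

## The measurement setting

A horse performs a standardized exercise test (SET). It is led in hand at
walk and trot before the SET (rested; trial label `pre`, the positive
class) and again after it (some level of fatigue; `post`). Seven inertial
measurement units — sacrum, withers, poll, and the lateral aspect of each
cannon bone — record tri-axial acceleration (g) and angular velocity
(deg/s) at 200 Hz. Maximum plasma lactate during the SET characterizes
exercise intensity: a group mean of at least 4.0 mmol/L (the anaerobic
threshold convention for Warmblood sport horses) labels the group's SET
high-intensity.

The analysis asks two questions: which biomechanical features change with
fatigue, and how well can a classifier separate `pre` from `post` using
only those features?

## The synthetic gait generator

The original recordings are not public, so the package ships a generator
whose defaults define the study conditions for all tests.

**Kinematic model.** Each stride is built from at most two
stride-frequency harmonics per channel, so accelerations are analytic
second derivatives and every trajectory is cyclic. Trunk and poll vertical
displacement uses the two-harmonic form
$d(\theta) = A_2\cos 2\theta + A_1\cos\theta$: it has exactly two peaks and
two troughs per stride, the peak difference is $2A_1$ (the prescribed
MaxDiff ground truth), and the troughs are equal, so the MinDiff ground
truth is exactly zero. $A_1, A_2$ are solved from the prescribed
displacement range and peak asymmetry. All other displacement and trunk
angle channels are single harmonics with fixed per-channel phases.

**Stance/swing structure.** Limb angular velocity is a smooth gate times a
swing-shaped oscillation. The gate is a smoothstep of the circular distance
to the swing centre: near zero during stance, near one during swing, with
edge half-width 2% of the stride. Its falling-edge midpoint *defines*
hoof-on and its rising-edge midpoint hoof-off, which gives the event
detector a physically motivated signature with an exact ground truth. Limb
angles are the cyclic integrals of the gated velocities, rescaled so the
integrated range of motion equals the prescribed value exactly.

**Speed.** The generator encodes forward speed as the per-stride sacrum
longitudinal excursion: that displacement range defaults to
`speed * stride_duration` (the stride length). The matching extractor
(`estimate_speed()`) divides the sacrum longitudinal cyclic-displacement
range (plus a configurable constant offset, default 0) by stride duration.
This is a deliberately simple, documented and pluggable stand-in for a
learned speed model; it is exact on the simulator and monotone in true
speed whenever longitudinal excursion scales with stride length.

**Gravity.** Emitted accelerations are gravity-compensated linear
accelerations. Real IMU data would need a gravity-removal stage before
cyclic integration; `lowpass()`/`cyclic_displacement()` leave a hook for
that but version 1 does not implement orientation-based gravity removal.

**Variability and noise.** Per-horse baselines are the configured gait
parameters jittered multiplicatively with CV `inter_horse_cv` (default
0.08); each stride is re-jittered with `stride_cv` (default 0.03); i.i.d.
Gaussian noise is added per sample (`noise_sd_accel` 0.02 g,
`noise_sd_gyro` 1 deg/s — a few percent of signal amplitude). There are no
bias, drift or misalignment terms. Fatigue effects are exact multiplicative
deltas applied to the post-trial parameters before any noise, so
ground-truth post/pre ratios equal `1 + delta` exactly; the default strong
set mirrors the documented fatigue signature (stance +10% at walk, swing
−10% at trot, front-limb longitudinal displacement −15%, hind-limb pro/ret
ROM −15%). Maximum lactate is drawn per horse from two normal
distributions, mean 4.04 (SD 1.80) mmol/L for the high-intensity arm and
1.62 (SD 0.57) for the low-intensity arm.

**What passing tests do and do not show.** The generator reproduces the
*structure* real gait data exhibits — periodic strides with stance/swing
phases, double-peaked vertical trunk motion, limb oscillation, inter-horse
and stride-to-stride variability, sensor noise — but not real equine
waveform morphology, surface or handler effects, asymmetric (lame) gaits,
or IMU artefacts such as drift and soft-tissue oscillation. Tests passing
on synthetic cohorts demonstrate that the pipeline's algorithms are
implemented correctly and recover known ground truth; they are not
evidence about classification accuracy on real horses.

## Preprocessing

All six channels of every stream are filtered with a 4th-order Butterworth
low-pass at 30 Hz, applied forward and backward. Zero-phase filtering was
chosen because event timings feed the duration features; the effective
magnitude response is the squared single-pass response. Filtering operates
about the channel mean so DC levels pass exactly. Note the digital filter's
analytic response carries the bilinear warping
$\tan(\pi f/f_s)/\tan(\pi f_c/f_s)$; far above the cut-off this differs
substantially from the analog prototype $1/(1+(f/f_c)^8)$, and the tests
check against the exact digital form.

The hoof-event detector is rule-based (the cited original used an external
learned model that cannot be reproduced): stance is where the smoothed
right-front gyroscope magnitude falls below `theta` (default 0.15) times a
rolling 95th-percentile envelope over about two stride periods (period
estimated by autocorrelation); stance onset is hoof-on, offset hoof-off.
Both edges are refined to the half-amplitude crossing of the local swing
level — matching the generator's edge-midpoint convention — and events too
close to the recording boundary to refine are discarded. Strides are the
half-open intervals between consecutive hoof-ons (1-based sample indexing,
`[start, end)`), and strides whose duration deviates more than 3 median
absolute deviations from the recording median are dropped, with a floor of
2 samples on the deviation threshold so sub-sample timing jitter on
quasi-constant durations is never flagged.

## Feature extraction: numerical choices

Angles are cumulative trapezoidal integrals of mean-removed angular
velocity; removing the stride mean discards any constant-rate component so
the per-stride angle closes on itself. Limb angular ROMs use per-axis
integration rather than full sensor-fusion orientation: only the per-stride
range is needed, not absolute orientation.

Displacements come from cyclic double integration: convert g to m/s²
(9.81), remove the stride mean, integrate, remove the *velocity* mean
(which is exactly the removal of the linear displacement trend), integrate
again, centre. Because the stride window is one period sampled half-open,
this closure is exact at the wrap-around point one sample past the window
(to machine precision), which is the correct cyclic constraint on a
half-open grid — an endpoint-equality detrend would tilt the series by
O(dt) and visibly bias the peak-difference features.

MaxDiff/MinDiff analyse the vertical displacement circularly (the stride
is one period), take the two largest maxima and two smallest minima, and
return `NA` (a logged missing-value sentinel; such strides are excluded
from aggregation) when the peak structure is absent — except for a
motionless, constant series, where both indices are defined as 0. Stance +
swing equals stride exactly by construction (swing is computed as the
difference).

## Feature table

Per horse and feature, pre+post strides are pooled and min–max normalized
to [0, 1]; a within-horse constant feature maps to 0 (degenerate rule).
Aggregation produces 52 means plus 52 variabilities per horse-trial;
variability is one of RMS, CV (= SD/mean, `NA` sentinel at zero mean),
sample SD (n−1 — the convention chosen here) or VAR. The validity floor is
33 strides per horse-trial (configurable). The classification unit is one
vector per horse-trial (two per horse); a sliding-window mode (33-stride
windows, 1-stride step) exists to mirror per-stride sample counts but is
off by default, because training on heavily overlapping windows of the
same horse-trial adds no independent information under
leave-one-subject-out folds.

## Selection and classification

The NCA variant weights features in an L1 per-feature distance,
$d(i,j)=\sum_f w_f^2\,|x_{if}-x_{jf}|$, and maximizes the expected
leave-one-out stochastic-neighbour accuracy minus $\lambda\sum_f w_f^2$
(default $\lambda = 1/n$) by BFGS with the analytic gradient from the
all-ones start; reported weights are $|w|$, hence non-negative and
permutation-equivariant. Ranking ties break by the canonical feature-table
order so results do not depend on column order.

Greedy forward selection evaluates LOSO accuracy on growing prefixes of
the ranking and stops at the first *strict* decrease ("decreased" read
strictly: equal accuracy continues). A consequence worth knowing: when
accuracy saturates at 1.0 early, the tie rule keeps adding features to the
end of the ranking, so perfect separability reports a large selected set.

Speed and the three gait-event durations are always computed and reported
alongside each fit (class means pre vs post), whether or not the ranking
selects them; they are not force-inserted into the classifier's feature
set by default (a flag exists) because membership is governed by the
ranking.

Classifier defaults: linear SVM with unit cost on the already-[0,1]
features; kNN with k = 5; decision tree with `minsplit = 4`,
`minbucket = 2` (the rpart defaults of 20/7 degenerate at LOSO sample
sizes of tens of rows); naive Bayes defaults; plain logistic regression.
Five algorithms are implemented. LOSO-CV holds out all samples of one
horse per fold; pooled predictions give one confusion table (positive
class `pre`), and per-fold metrics provide the mean ± SD summaries. The
pipeline's loop nesting (variability metric outer, classifier inner) does
not affect which (metric, classifier) combination wins a cell, since the
best is taken over the full cross product.

## A calibration caveat

Following the original workflow, NCA weighting and greedy selection run on
the full subset *before* leave-one-subject-out evaluation. This leaks
test-fold labels into feature selection: on pure-noise feature matrices
(80 samples × 104 features) the end-to-end LOSO accuracy is optimistically
biased by roughly +0.1 rather than centred at 0.5, while `loso_cv()` on a
fixed feature set is properly calibrated. The package implements the
workflow faithfully and exposes the unbiased building block; users wanting
leakage-free estimates should nest selection inside each fold.

## Problem sizes used by the tests

Unit tests run on 2–3-horse cohorts of 5–6 strides. The recovery
experiment uses a 20-horse, 33-strides-per-trial, zero-sensor-noise cohort
at both gaits (2800 strides); the selection-soundness experiment uses 20
replicates of a 20-horse feature matrix with three injected effects at 3×
the noise SD; the end-to-end experiments use a 20-horse strong-effect
walking cohort and a 40-horse zero-effect null cohort. These sizes were
chosen so each experiment exercises the full pipeline at a scale a single
workstation reproduces in about two minutes.

## Known limitations

- The harmonic stride model is a stand-in, not a claim about true equine
  IMU waveforms; detector thresholds tuned on it may need adjustment on
  real data.
- No gravity removal, sensor-fusion orientation, drift or bias handling.
- The speed model is a displacement-based proxy, not a validated estimator.
- Binary fatigue only; no graded fatigue levels, lameness, surface or
  rider/handler effects.
- The selection-before-validation leakage described above is inherited
  from the workflow the package reproduces.
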