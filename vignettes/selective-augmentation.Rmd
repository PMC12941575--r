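---
title: "Class-selective time-warping augmentation for gait classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-selective time-warping augmentation for gait classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitwarp)
```

## The problem

Classifiers of pathological gait from wearable inertial signals almost always
face severe class imbalance: healthy controls are easy to recruit, patients
are not. The standard remedy — synthetic oversampling of the minority class,
or blanket augmentation of everything — treats augmentation as a purely
statistical operation. But the two classes are not statistically exchangeable:
healthy locomotion carries rich, serially correlated stride-timing
variability, while Parkinsonian gait is marked by reduced variability and
dynamical complexity. Injecting artificial variability into healthy signals
can erase exactly the structure that distinguishes them; injecting a
controlled amount into pathological signals expands the minority class while
staying inside physiologically plausible timing bounds.

`gaitwarp` implements this physiology-informed, class-selective augmentation
strategy end to end: a synthetic cohort generator with a ground-truth class
contrast, the fixed preprocessing and segmentation chain, smooth time-warping
applied selectively by class, Random-Forest channel selection, a compact
CNN–LSTM segment classifier, and an experiment harness that compares the four
augmentation regimes (`NONE`, `HEALTHY_ONLY`, `FULL`, `PD_ONLY`) and sweeps
augmentation intensity.

## The warp operator

The augmentation primitive is a smooth, monotone, endpoint-preserving
remapping `w` of a segment's time axis, evaluated on the sample grid
`0 … L−1`:

1. place `k + 2` knots uniformly on `[0, L−1]` (default `k = 4` interior
   knots);
2. draw one multiplicative factor `g_j = max(0.05, 1 + N(0, σ))` per
   inter-knot interval;
3. cumulate the factors, rescale so the first knot maps to 0 and the last to
   `L−1`;
4. interpolate the knot images with a monotone (Hyman-filtered) cubic spline.

Every channel of a segment is then linearly interpolated at `w(t)`. Design
points worth stating explicitly:

* **One warp per segment, shared across channels.** Warping channels
  independently would destroy inter-sensor coordination; sharing the warp
  perturbs timing while leaving the multivariate amplitude structure intact.
* **The positivity clip at 0.05** guarantees strictly increasing knot images
  for any `σ`, so monotone interpolation yields a strictly increasing map and
  warped time never folds back. The clip only binds in practice once
  `σ` approaches 0.5 and above.
* **`σ = 0` is exactly the identity**, which gives a clean degenerate case:
  augmentation with `σ = 0` is duplication-only oversampling.
* **Unbiasedness.** The construction is symmetric around the identity; the
  Monte-Carlo mean of `w(t)` over thousands of draws stays within 2 samples
  of `t` everywhere (checked in the test suite at σ = 0.2, L = 125).
* **Output length is forced back to `L`** by evaluating on the original
  grid, so synthetic segments remain pipeline-compatible.

The defaults — five variants per targeted segment at `σ = 0.2` — are the
selective-augmentation setting whose behaviour the harness examines; the knot
count and interpolation scheme are exposed in `warp_config()` because the
method is defined up to these choices.

Augmentation policies target classes, not segments: `PD_ONLY` appends five
warped variants of every Parkinsonian training segment and passes healthy
segments through untouched; `HEALTHY_ONLY` and `FULL` are the symmetric and
blanket controls. Originals are always retained alongside their variants, and
`augment_dataset()` refuses synthetic input so variants are never compounded.
Augmentation is applied to the training side only, after the split, so a
validation segment never has a parent or child in training.

## Preprocessing chain

The conditioning chain is fixed in order and is a pure function of the
recording and its configuration: resample to 25 Hz → Savitzky–Golay smoothing
→ Butterworth low-pass → per-channel z-normalization → non-overlapping
125-sample (5 s) windows anchored at the first sample, with windows containing
non-finite values excluded and the trailing remainder dropped.

Parameters the chain exposes, with defaults and rationale:

| parameter | default | why |
|---|---|---|
| `target_rate_hz` | 25 Hz | working rate of the pipeline; 5 s windows = 125 samples |
| `sg_window`, `sg_polyorder` | 11, 3 | 0.44 s cubic window: removes jitter, reproduces degree-≤3 structure exactly, preserves gait events |
| `butter_order`, `butter_cutoff_hz` | 4, 6 Hz | locomotor content lives below ~6 Hz; order 4 gives a sharp yet stable roll-off |
| `zero_phase` | TRUE | forward–backward filtering cancels phase distortion of event timing; gain at the cutoff becomes 0.5 |

Numerical details: channels are mean-centred before Butterworth filtering and
the mean restored afterwards, so constant signals pass through exactly and
start-up transients stay small; zero-variance channels z-normalize to
all-zeros with a warning rather than NaNs; resampling is linear interpolation
on a uniform grid (behaviour pinned against closed-form sinusoids in the
tests).

## The synthetic cohort

The study conditions this package targets involve a private clinical dataset,
so the simulator is a first-class module rather than a test fixture: it
generates cohorts whose class contrast is known by construction, giving every
downstream claim an exact oracle.

Signals are synthesised **event-first**. Stride-onset times are drawn per
subject: healthy intervals have mean 1.10 s and CV 0.04 with lag-1
autoregressive structure (coefficient 0.4) — the simplest model of
"structured variability"; Parkinsonian intervals have mean 0.95 s and CV
0.015, drawn independently. The instantaneous stride phase interpolates
between onsets, and each of the 8 informative channels sums class-specific
numbers of harmonics of that phase (5 for healthy, 2 for Parkinsonian) with
channel-specific amplitudes and phase offsets fixed across subjects.

Two further class-differential variability mechanisms model the "motor
entropy" contrast, both event- or band-structured rather than free
parameters of convenience:

* **stride-to-stride amplitude gains** — each stride's motor output is
  scaled by `1 + N(0, CV)` with CV 0.10 for healthy subjects and 0.02 for
  Parkinsonian ones (healthy movement fluctuates in size; bradykinetic
  output is stereotyped);
* **band-limited motor noise** — a stochastic component low-passed at 5 Hz
  (inside the locomotor band, so preprocessing preserves it) with SD 0.25
  for healthy and 0.05 for Parkinsonian channels, modelling the continuous
  micro-adjustments of adaptive neuromuscular control.

The second mechanism is what carries the sample-entropy ordering. Harmonic
count alone cannot: richer harmonic content makes local waveform shapes
*more* distinctive, so two-point template matches extend to three points
more reliably and SampEn falls — a near-sinusoidal signal accumulates
spurious non-extending matches and scores *higher*. Genuine unpredictability
must therefore come from a stochastic, physiologically motivated component,
which is also how complexity is understood in the motor-control literature.

The 8 noise channels are low-pass-filtered white noise with a law identical
in both classes, so channel ranking has a recoverable ground truth
(`informative_channels()`). Measurement noise (SD 0.15) is added everywhere.
The native rate is 100 Hz so the resampling stage is genuinely exercised.

The event log returned with every recording is the exact ground truth:
`stride_interval_cv()` applied to it recovers the configured CV contrast
without any signal processing, and sample entropy of informative channels
orders healthy above Parkinsonian.

These magnitudes are modelling choices for a plausible class contrast, not
clinical claims about Parkinson's disease. What the simulator deliberately
does **not** model: biomechanical skeletons, sensor drift, magnetometer
interference, inter-subject anatomical variation, medication state, or any
within-class heterogeneity beyond stride timing and noise. Consequently the
synthetic classes are cleanly separable, and experiments on them demonstrate
*orderings and invariances* of the augmentation strategies — not absolute
accuracy levels transferable to clinical data. With generous recordings the
segment-level task saturates for every policy; the harness keeps recordings
short (below) so the comparison remains informative about relative behaviour
under scarce data.

## Classifier

The segment classifier is a compact CNN–LSTM implemented in RcppArmadillo:
1-D convolution blocks over time (convolution → batch normalization → ReLU →
max-pool → dropout), an LSTM over the pooled time axis whose final hidden
state feeds a dense two-class softmax, trained with Adam (learning rate
0.001, batch size 32) on categorical cross-entropy. Exact layer sizes are
configuration; the experiment harness uses filters (8, 16) with kernel 5,
16 LSTM units, and dropout 0.3 — small enough that a full policy comparison
runs on one CPU in minutes. Epochs are fixed (default 40, no early stopping)
so learning curves are comparable across augmentation policies.

All randomness — initialization (Glorot uniform), shuffling, dropout masks —
derives from one seed, so training is bit-reproducible. The analytic
gradients of every layer are verified against central finite differences in
the test suite (relative error below 1e-4 at machine-precision step sizes).
Class imbalance is handled only through augmentation, never class weights,
since the imbalance response is exactly what the experiments measure.

## Channel selection

Channels are ranked by Random-Forest importance computed on five per-channel
summary features per segment (mean, SD, RMS, mean absolute first difference,
dominant-frequency power fraction); a channel's importance is the sum of its
features' impurity importances, renormalized. Summaries rather than raw
125-sample vectors keep importances attributable to channels. Ranking is fit
on training-split originals only — augmented variants duplicate temporal
structure and would inflate importances. Selection (`select_channels()`) is a
pure projection onto the top-`k` channels; the harness uses `k = 8`, matching
the simulator's informative-channel count, and recovery of all 8 from 16 is
itself an acceptance property.

## Evaluation and experiments

`compute_metrics()` treats Parkinsonian gait as the positive class. The ROC
curve sweeps all distinct scores; the AUC is the trapezoidal integral, which
equals the ordered-pair statistic with ties counted one half (asserted
against a brute-force pair count in every test run). Sample entropy
(`sample_entropy()`, default `m = 2`, `r = 0.2 × SD`, Chebyshev distance,
self-matches excluded) serves as the complexity diagnostic; the compiled
implementation is checked for exact equality against a naive O(N²) oracle.

`compare_strategies()` runs the full pipeline per policy and seed. Within a
seed, all policies share the same preprocessed segments, the same stratified
80/20 split, and the same channel ranking bit-for-bit; only augmentation
differs, so differences in validation metrics are attributable to policy.
Validation contains originals only. Aggregation reports mean ± SD over seeds
— dispersion is an extension beyond single-number summaries, made possible by
seeded replication. `sweep_envelope()` repeats the selective policy over a
grid of augmentation factors and warp intensities to probe the range within
which added temporal variability helps — past it (e.g. σ = 1.0, where the
positivity clip binds and warps become extreme), synthetic variants stop
resembling gait and performance degrades or at best stagnates.

Evaluation is segment-level by design, mirroring the study setting this
package examines; segments of one subject can land on both sides of the
split, which makes absolute numbers optimistic relative to
subject-independent validation. This is a known limitation of the design
being studied, not an accident of the implementation.

## Problem sizes

The experiment harness and acceptance checks use, as the package's own
desk-scale choices: the default cohort composition (48 healthy / 8
Parkinsonian subjects, 16 channels) with 60 s recordings (12 segments per
subject), the compact model above, 40 epochs, and 5 seeds (3 in the
acceptance script). Simulator-fidelity diagnostics use the full default
180 s recordings over 20 subjects per class. Warp-operator properties are
checked over 10,000 seeded draws. Recording length matters: much shorter
recordings leave the policy orderings inside single-segment seed noise,
while much longer ones saturate every policy at 100% segment-level
accuracy; 60 s is the shortest length at which the orderings resolve
cleanly on this cohort.

## Known limitations

* The synthetic class contrast is strong; real Parkinsonian gait
  classification is far harder, and passing orderings here do not certify
  clinical performance.
* Segment-level (not subject-independent) evaluation, as discussed above.
* The warp construction is one standard realization of "smooth time-warping
  with Gaussian perturbations"; results are reported as functions of its
  configuration (knot count, clip, interpolation scheme).
* Only time-warping is implemented — no magnitude warping, jittering,
  rotation, or mixup.
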