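# gaitwarp

Class-selective time-warping augmentation for gait-pattern classification
from multichannel wearable inertial signals.

## The problem

Clinical gait datasets are small and imbalanced: many healthy controls, few
patients. Data augmentation is the usual fix, but blanket augmentation
ignores a physiological asymmetry — healthy locomotion carries rich,
serially correlated stride-timing variability, while Parkinsonian gait shows
reduced variability and dynamical complexity. Perturbing healthy signals
risks destroying the very structure that identifies them; perturbing
pathological signals within plausible timing bounds expands the minority
class without distorting it.

`gaitwarp` implements and evaluates this **selective augmentation** idea as
a complete pipeline:

* **Smooth time-warping** — the augmentation operator. A segment's time axis
  is remapped by a strictly increasing, endpoint-preserving map `w` built
  from uniformly placed knots whose spacings are scaled by
  `max(0.05, 1 + N(0, σ))`, cumulated, rescaled, and interpolated with a
  monotone cubic spline. All channels of a segment share one warp. Default
  intensity σ = 0.2, five variants per targeted segment.
* **Augmentation policies** — `NONE`, `HEALTHY_ONLY`, `FULL`, `PD_ONLY`
  (the selective strategy), applied to training data only.
* **Preprocessing chain** — resampling to 25 Hz, Savitzky–Golay smoothing,
  zero-phase Butterworth low-pass (6 Hz), per-channel z-normalization, and
  non-overlapping 125-sample (5 s) windows.
* **Channel selection** — Random-Forest importance over per-channel summary
  features, retaining the top-k channels.
* **Classifier** — a compact CNN–LSTM (1-D conv blocks → LSTM → softmax)
  with batch normalization and dropout, trained with Adam (lr 0.001, batch
  32), implemented in RcppArmadillo with bit-reproducible seeding.
* **Evaluation** — accuracy, sensitivity/specificity (PD positive), ROC/AUC
  (trapezoidal, equal to the tie-aware ordered-pair statistic), sample
  entropy and stride-interval CV diagnostics, a four-policy comparison
  harness, and an augmentation-intensity sweep.
* **Synthetic cohort generator** — event-first simulation of labelled gait
  recordings with a ground-truth class contrast (stride-interval CV 0.04
  with AR(1) structure vs 0.015 independent; 5 vs 2 harmonics; 8 informative
  among 16 channels; 48 healthy vs 8 Parkinsonian subjects by default), so
  every claim has an exact oracle.

## Worked example

```r
library(gaitwarp)

# a small imbalanced cohort: 12 healthy, 4 Parkinsonian subjects
cohort <- simulate_cohort(simulator_config(n_healthy_subjects = 12,
                                           n_pd_subjects = 4,
                                           duration_s = 30, seed = 42))

# ground-truth stride-timing contrast from the simulator's event logs
cv <- vapply(cohort, function(r) stride_interval_cv(r$event_log), numeric(1))
lab <- vapply(cohort, function(r) r$label, character(1))
round(tapply(cv, lab, mean), 4)
#> HEALTHY      PD
#>  0.0404  0.0156

# compare augmentation policies (small model, 2 seeds for illustration)
res <- compare_strategies(
  cohort,
  model = model_config(conv_filters = c(8, 16), lstm_units = 16,
                       epochs = 40),
  seeds = 1:2, retained_k = 8)
res$summary[, c("policy", "mean_accuracy", "mean_auc")]
#>         policy mean_accuracy  mean_auc
#> 1         NONE     0.8684211 0.9785714
#> 2 HEALTHY_ONLY     0.9736842 1.0000000
#> 3         FULL     1.0000000 1.0000000
#> 4      PD_ONLY     0.9473684 1.0000000
```

The simulated healthy subjects show the configured stride-interval
variability contrast (CV ≈ 0.04 vs ≈ 0.016), recovered exactly from the
ground-truth event logs. In the comparison, validation accuracy is computed
on held-out original segments only; within a seed every policy shares the
same split and channel ranking, so differences are attributable to
augmentation alone. With so little data the unaugmented baseline misclassifies
part of the held-out set (accuracy 0.87), while every augmented policy
improves on it. On this synthetic cohort the class contrast is strong, so
augmented policies approach saturation quickly; the informative quantity is
the ordering (selective augmentation beating the baseline), not the absolute
level — two seeds on 16 subjects is an illustration, not the experiment (see
`compare_strategies()` with the default cohort for that). See the methods vignette
(`vignettes/selective-augmentation.Rmd`) for what the simulator does and
does not emulate, and therefore what these numbers do and do not show.

A thin command-line front end is included at `inst/cli/gaitwarp.R`
(`simulate`, `run`, `compare` subcommands over YAML/JSON configs).

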