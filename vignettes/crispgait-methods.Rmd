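---
title: "Gait-based Parkinson's screening with crispgait: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-based Parkinson's screening with crispgait: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Parkinson's disease alters gait long before overt motor symptoms: strides
lengthen in time, stance occupies a larger fraction of the cycle, cadence
and walking speed drop, and stride-to-stride variability and left/right
asymmetry grow. In-shoe force-sensitive resistors record the vertical
ground-reaction force (VGRF) of each foot at 100 Hz, and these timing
signatures can be read off the force trace. `crispgait` implements a
complete screening pipeline over such recordings:

1. **Preprocess** each walk: per-channel min--max normalization to
   [0, 1], removal of the first 20 s and last 10 s of the walk (gait
   initiation and termination), and a kernel-9 median filter.
2. **Detect gait events**: a heel strike (HS) is an upward crossing of
   20% of the channel's peak force, the following downward crossing is
   the toe off (TO); a gait cycle spans two successive same-foot heel
   strikes.
3. **Extract per-cycle features**: stride, stance, and swing times and
   percentages, cadence (`120 / stride_time`), step and stride length,
   speed, stance:swing ratio, trailing-window variability, and
   left/right asymmetry indices.
4. **Curate the panel** (the pipeline's core): Pearson correlation
   pruning at rounded `|r| >= 0.80`, discarding the lower
   mutual-information member of each flagged pair, then recursive
   feature elimination (RFE) wrapped around a 100-tree random forest
   down to 10 features.
5. **Balance classes** with SMOTE (synthetic minority oversampling):
   each synthetic row is `x_i + delta * (x_zi - x_i)` with
   `delta ~ U[0, 1]` and `x_zi` one of the `k = 5` same-class nearest
   neighbors of `x_i`, generated until every class matches the majority
   count.
6. **Classify and evaluate**: KNN, decision tree, random forest, and two
   gradient-boosted tree models under 5-fold cross-validation, scored at
   the cycle level and, separately, after collapsing each subject's cycle
   predictions into a single patient decision by majority/modal vote with
   mean-posterior tie-breaks.

Stages 4 and 5 are fitted strictly inside each training fold; a leakage
guard object seals held-out labels and raises an audit error on any read
during fitting.

## The synthetic cohort generator

The package ships a first-class simulator so every stage is testable
without the clinical dataset. Each foot's force is a train of
*double-bump* stance templates — a loading-response hump and a push-off
hump from a raised-cosine envelope times a two-humped shape — supported
on [HS, TO] and zero in swing, plus Gaussian sensor noise. Ground-truth
event times and per-cycle timings are recorded exactly.

Timing follows a severity-score model: a healthy control has severity 0
and a PD subject at Hoehn--Yahr stage *h* has severity *h*. Per severity
unit the defaults shift stride time by +0.035 s, stance fraction by
+0.010, and walking speed by −0.07 m/s, all scaled by a single
`severity_gradient` knob (0 gives a null cohort). Around the
healthy-control anchors (stride 1.05 s, stance fraction 0.62, speed
1.25 m/s — ordinary adult walking), subjects draw random effects once
(SDs 0.03 s, 0.010, 0.06 m/s) and share them across their walks, so
between-subject variance dominates within-subject variance and
subject-wise evaluation differs meaningfully from cycle pooling.

Two secondary signatures are also simulated because they are genuine
disease markers and several panel features exist to capture them:
within-walk cycle variability (per-cycle SDs grow by 25% per severity
unit) and left/right stance asymmetry (a per-subject stance-fraction
offset whose spread grows by 25% per severity unit). Without them,
variability and asymmetry columns would be pure subject-level noise, and
fold-level feature selection would exploit them to memorize training
subjects rather than the class signal.

Numerical choices worth knowing:

* The template's rise/fall time constant is 8 ms. VGRF loading
  transients are fast, and a steep edge keeps the 20%-of-peak crossing
  within a few milliseconds of the true event, so detected stance times
  carry no visible bias at 100 Hz.
* The right foot is phase-locked to the left (half a stride offset plus
  jitter tied to the cycle-timing SD), as in coupled human gait;
  independently generated feet drift out of phase over a 60-s walk.
* Sensor channels split each foot's total by fixed nonnegative weights
  summing to 1; downstream computation uses totals only.

What the simulator does **not** emulate: dual-task or treadmill walking,
drift or baseline wander in the sensors, per-sensor spatial dynamics
(center-of-pressure), freezing episodes, or the real cohort's
demographics. Passing tests therefore demonstrate that the pipeline's
machinery is correct and leak-free under known ground truth — not that
the clinical accuracy figures transfer to any particular dataset.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `head_trim`, `tail_trim` | 20 s, 10 s | walk head/tail excluded before analysis |
| `median_kernel` | 9 samples | median-filter window (odd) |
| `threshold_frac` | 0.2 | HS/TO threshold as a fraction of peak force |
| `r_threshold` | 0.80 | rounded-&#124;r&#124; pruning cutoff |
| `n_keep` | 10 | features surviving RFE |
| `n_trees` | 100 | random-forest size inside RFE |
| `k_neighbors` | 5 | SMOTE neighborhood |
| `n_folds` | 5 | outer cross-validation folds |
| `window` | 10 cycles | trailing window for variability features |

The event threshold is proportional to each channel's peak, so detection
is invariant to min--max normalization (tested); the stated order
normalize → trim → filter is followed anyway.

## Numerical and design choices

* **Median filter edges** use reflect padding, so output length equals
  input length and trim boundaries produce no edge artifacts.
* **Sub-sample event timing**: crossings are linearly interpolated
  between the bracketing samples, reducing 100-Hz quantization.
* **Debounce**: crossings within 100 ms of the previous accepted event
  of the same kind are ignored.
* **Cycle validity** bounds (stride 0.4--2.5 s, stance fraction
  0.40--0.90) mark implausible cycles `valid = FALSE` with a reason code
  instead of dropping them silently.
* **Stride length is a model, not a measurement**: VGRF alone carries no
  distance information, so `stride_length = reference_speed x
  stride_time`, with the reference speed taken per subject from
  demographics when available. Step length splits the stride by the
  walk's mean step-time fractions (opposite-foot heel strikes), falling
  back to an even split.
* **MI estimator**: 10 quantile bins + plug-in contingency MI — always
  nonnegative, invariant to monotone transforms, deterministic. MI ties
  during pruning drop the lexicographically later name; correlated
  chains are resolved greedily by descending rounded `|r|` with
  re-checking, which guarantees the testable post-condition that no
  retained pair remains at or above threshold.
* **RFE** eliminates one feature per iteration (finest ranking at
  negligible cost for panels of this size). When pruning leaves fewer
  than `n_keep` columns — possible with the default 20-column panel on
  small folds — the pipeline keeps all survivors rather than erroring;
  `rfe_select()` itself enforces its contract strictly.
* **SMOTE base rows** are visited round-robin in original order rather
  than sampled, trading a little classical randomness for coverage and
  seed-reproducibility; distances use per-fold standardized columns.
  Every synthetic row's `(base, neighbor, delta)` is recorded so the
  interpolation identity can be audited to 1e-9.
* **Folds are subject-grouped by default for both protocols** (no
  subject straddles train and test); the protocols differ only in
  whether metrics are computed on pooled cycles or on voted subjects. A
  `cycle_stratified` mode exists to emulate per-cycle splitting, which
  is optimistic because the same subject's cycles appear on both sides.
* **Gradient boosting backends**: both boosted models run on xgboost;
  the `GB` adapter fixes the L1/L2 regularization terms to zero, which
  reduces the regularized objective to the plain gradient-boosting
  update, while `XGB` exposes `lambda`. The adapters assert only the
  probabilistic output contract (rows sum to 1, argmax = label).
* **Metrics**: PD is the positive class; multiclass metrics are macro
  one-vs-rest, AUC is macro one-vs-rest on posteriors. Zero
  denominators yield 0. Paired baseline-vs-CRISP comparisons use
  two-sided paired t-tests over folds with no multiplicity correction;
  identical samples report p = 1 and constant nonzero differences are
  flagged as zero-variance rather than given a fake p.
* **Determinism**: one master seed fans out to per-stage streams
  (`stage_seed()`); xgboost runs single-threaded, so a full experiment
  is bit-reproducible.

## Problem sizes used by the shipped checks

The test suite validates event recovery on 50 clean + 50 noisy simulated
walks, the pruning post-condition on 200 random 500 x 30 matrices with
injected collinear columns, RFE recovery on a planted-signal design
(10 informative + 20 noise columns, n = 2000, 10 seeds), and end-to-end
discrimination on five 40-subject cohorts in a strongly separated regime
(severity gradient 3, 2 N sensor noise), where the curated XGB
configuration is expected to reach at least 95% mean subject-wise
accuracy. `scripts/acceptance.R` recomputes scaled-down versions of the
same quantities from scratch at whatever seed it is given.

## Known limitations

* The ~30-column panel of the original experimental setup is not fully
  recoverable; the default panel here has 20 columns and is
  config-driven, so pruning arithmetic (how many features fall at the
  0.80 cutoff) differs from the published counts.
* Severity grading assumes stages {1, 2, 3}; other stage sets are
  configurable.
* Subject-wise AUC uses per-subject mean posteriors; other collapsing
  choices are defensible.
* No frequency-domain, entropy, or center-of-pressure features, no
  SMOTE variants, no neural models — deliberately out of scope.
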