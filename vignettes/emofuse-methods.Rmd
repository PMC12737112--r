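---
title: "Methods: late-fusion emotion recognition from biosignals and facial labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: late-fusion emotion recognition from biosignals and facial labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emofuse)
```

## Overview

`emofuse` implements a two-scheme, decision-level-fusion pipeline for
frame-level emotion recognition from synchronized wearable biosignals
(EDA, HR, TEMP) and a facial-analysis label stream, in populations where
labels are scarce, noisy and heavily imbalanced. This vignette is the
package's own account of the models, the tunable parameters, the numerical
choices, and what the synthetic-data experiments do and do not show.

## Label aggregation

Three annotators assign one categorical label per second from the six
Ekman emotions plus `contempt`; seconds with no selection are `other`.
`contempt` has no counterpart in the facial stream and is discarded by
normalizing it to `other` **per vote, before aggregation** — a design
choice worth spelling out: the alternative reading (remapping only
intervals whose *majority* is contempt) differs exactly when one or two
votes are contempt. The per-vote rule keeps the two schemes consistent: a
contempt vote carries no probability mass in the proportional scheme and
cannot form a majority in the categorical one.

* **Method I** takes the label chosen by ≥ 2 annotators; three-way
  disagreement yields `other` (no dominant emotion).
* **Method II** averages the three votes into a 6-vector of thirds over
  the modeled emotions; `other` votes contribute nothing, and a second
  with no modeled-emotion vote is the all-zero vector.

The canonical emotion order everywhere a 6-vector is indexed is
`happy, sad, scared, disgusted, surprised, angry`. Argmax ties in
`dominant_from_distribution()` break to the lowest class index — the
choice is arbitrary but deterministic and documented; the all-zero vector
maps to `other`.

## Synchronization and preprocessing

Wristband channels carry absolute start epochs in their file headers; the
face log and annotations are session-relative. Second *t* of the session
clock is the half-open interval `[t, t + 1)` — the boundary convention is
ours, chosen so every sample belongs to exactly one bin. EDA/TEMP (4 Hz)
are averaged within bins; HR (1 Hz) passes through natively; facial change
points are forward-filled, with `other` before the first event (no face
seen yet). The timeline ends at the earliest stream end; channels starting
late contribute missing values rather than truncating the session.

Signals are z-scored **per subject over the subject's full recording**
using the population (divide-by-N) standard deviation; neither choice is
dictated by first principles, so both are fixed and documented (the
sample-SD alternative changes values by a factor `sqrt((n-1)/n)`, far
below the effect sizes of interest). Constant channels map to zero with a
warning. The retained native 4 Hz arrays are standardized with the same
per-subject parameters so upsampled samples live on the model's input
scale; the parameters themselves are estimated from the 1 Hz aligned
stream.

Windows are 4 s long with a 2 s stride (50% overlap). Windows containing
a missing biosignal second are dropped rather than imputed — wristband
recordings of this population have substantial dropout, no principled
1 Hz imputation exists for these channels, and imputing would blur the
masking semantics.
Frames whose label is `other` (Method I) or the zero vector (Method II)
are *retained in the inputs* and excluded only from the loss through a
per-frame binary mask; the two schemes' masks differ exactly on three-way
disagreements (mass without majority).

## Models and training

All models are sequence-to-sequence: one 6-vector per timestep of the
4-frame window. This is the only output convention under which per-frame
loss masking and per-frame fusion features are simultaneously coherent; a
sequence-to-one head would have to collapse frames with mixed validity.

| model | architecture | output | loss |
|---|---|---|---|
| Method I signal (EDA/HR/TEMP) | BiLSTM(128) → dense 64, 32 (ReLU) | softmax | masked CCE |
| Method II signal | BiLSTM(128) → dense 128, 64 (ReLU) | sigmoid | masked MSE |
| Method II face | per-timestep dense 64 (ReLU) | sigmoid | masked MSE |
| Method II fusion | BiLSTM(64) over 4 × 24 → dense 64 | sigmoid | masked MSE |

Under Method I the facial stream is *not* modeled: the forward-filled
dominant label enters fusion directly as a one-hot block. The Method II
face model's six-value-per-timestep input is the one-hot encoding of that
same forward-filled label — the event log provides only dominant labels,
so this model is what turns the categorical facial stream into graded
intensities. The width of the Method II fusion recurrence (64 per
direction) is our choice; the layer's existence and its 64-unit ReLU
interaction layer are fixed.

Training is minibatch Adam (rate `1e-3`, batch 32), seeded and
deterministic. Method I trains up to 100 epochs with early stopping at
patience 10 on validation loss; Method II uses fixed budgets (40 epochs
unimodal, 50 fusion). In all cases the parameters achieving the lowest
validation loss are restored — for the fixed-budget schedules this
best-checkpoint rule substitutes for early stopping. The masked losses
average over valid frames only (CCE) or valid frame × channel entries
(MSE); a fully masked batch contributes zero loss *and zero gradient*, and
log arguments are clipped at `1e-7`. The forget-gate bias is initialized
to 1, other weights Glorot-uniform, biases zero. The numerical kernels
(BPTT, Adam) are compiled; their gradients are checked against central
finite differences in the test suite.

Parameter counts are pure functions of the spec (`n_params()`): the
Method I signal model has 151,846 parameters, which the tests assert.

## Splitting, filtering, balancing

Subjects are split 60/20/20 (train/val/test) greedily on per-subject
frame counts, seed-shuffled among ties, so realized fractions track the
targets when session lengths vary; no subject appears in two partitions,
which the pipeline re-asserts at run time. Only the training partition is
filtered and balanced:

* **Method I filtering** drops windows containing only `other`/`happy`
  frames, unless the window has *exactly one* happy frame ("fewer than
  two but at least one"). We read the filtering unit as the 4 s window —
  the only sequence unit the pipeline defines.
* **Method II filtering** drops all-zero windows and windows whose only
  mass is happy *with* at least one zero frame; all-happy windows stay.
* **Upsampling** appends, for each distinct training second whose
  dominant emotion is `disgusted`, `surprised` or `angry`, exactly one
  4-frame sample built from the native 4 Hz EDA/TEMP samples of that
  second, the HR value repeated, and the labels copied. Method II
  dominance is judged by argmax of the target distribution, mirroring the
  Method I rule. Validation and test sets are never resampled.

## Fusion

Per-second unimodal predictions (overlapping windows averaged, Method I
scores renormalized) are concatenated in the fixed order EDA, HR, TEMP,
FACE into 24-dim features. Method I fits a multinomial logistic
regression on the valid frames with inverse-class-frequency weights and
an L2 penalty (`lambda = 1` by default; no principled strength exists a
priori, so the value in force is logged with every run); the fit minimizes the penalized weighted NLL by BFGS from a
zero start and is deterministic. Method II feeds per-window 4 × 24 fused
sequences to the recurrent fusion network. The fused system always
outputs one of the six emotions; there is no abstention class.

Two stacking protocols exist: by default the fusion model is fitted on
predictions for the (unaugmented) training sequences, with the validation
split used only for checkpoint selection — the two-stage protocol;
`fusion_train = "val"` instead fits fusion on held-out validation
predictions (classic stacking). The two-stage default keeps the
validation split strictly out of parameter fitting. Augmented
samples shape the unimodal models only — the categorical fusion handles
imbalance through its class weights instead, and per-second features are
undefined for samples that live on a synthetic 4 Hz time base.

## Evaluation

The categorical report computes accuracy, balanced accuracy, micro/macro
precision/recall/F1, Hamming loss and per-class support, on frames whose
true label is a modeled emotion. Under this single-label, always-predict
regime the identities `micro-F1 = accuracy`, `balanced accuracy = macro
recall` and `hamming = 1 − accuracy` hold exactly — the Hamming loss is
computed on class assignments (misclassification rate), the only
convention consistent with those pairings. Macro averages are unweighted
over all six classes; classes absent from the truth contribute recall 0
(flagged, since the alternative — averaging over present classes —
changes numbers on small test sets). The regression report gives
per-emotion MSE/MAE over valid frames and per-emotion cosine similarity
between predicted and true time series; the overall MSE/MAE is the
unweighted mean of the six per-emotion values. Because "overall" cosine
is ambiguous, both views are reported: the mean of per-emotion cosines
(`cosine_overall`) and the mean per-frame cosine (`cosine_frames`).
Method II outputs are additionally mapped to dominant labels per frame
and pushed through the categorical suite, enabling a like-for-like
comparison of the two schemes. Confusion matrices are row-normalized
percentages, printed to one decimal.

## The synthetic generator

`generator_config()` emulates the *structure* of the target recordings:

* a semi-Markov latent emotion track with geometric dwell times (default
  mean 8 s) and a skewed stationary law (default happy 45%, other 35%,
  4% per minority emotion). Because the next state is drawn from the
  stationary law excluding the current state, the per-state mean dwell is
  scaled by `1/(1 − π_state)`, which makes long-run frequencies converge
  exactly to the configured law;
* three conditionally independent annotators with agreement `α` (default
  0.8) and uniform confusion, including contempt at a configurable rate
  (default `1/7`, i.e. uniform over all non-latent labels);
* a face stream with per-second detection probability (default 0.85) and
  label confusion (default 0.1), logged as change points only, so
  forward-fill bridges detection gaps;
* biosignals at native rates: EDA = baseline + exponentially decaying
  phasic bump at episode onsets (time constant 3 s), HR = baseline +
  additive offset, TEMP = first-order drift toward a per-emotion
  setpoint, each plus AR(1) noise. Baselines are drawn per subject from
  physiologically plausible ranges (EDA 1–8 µS, HR 70–110 bpm, TEMP
  31–34 °C).

Defaults were chosen once as qualitatively realistic for this population
and are not tuned against test outcomes. Two presets define the study
conditions of the synthetic experiments: `recovery_config()` (12 subjects
× 600 s, perfect annotators and face detection, strongly separated
effects, moderate skew) for parameter recovery, and
`complementary_config()` (9 subjects × 400 s, no face stream, each
emotion pair separable on exactly one channel) for the fusion-benefit
property. Those sizes are the experiment definition; the unit-test
fixtures are smaller. A `shuffle_effect_labels` switch generates
biosignals from a permuted latent track — the label-permutation null
under which signal models must fall to chance.

What passing these experiments shows: the pipeline is internally
consistent, leak-free across subjects, and able to recover planted
structure through both fusion routes. What it does not show: performance
on real recordings — the generator has memoryless episode dynamics, no
movement artifacts, no annotator bias structure (confusion is uniform),
and biosignal effects far cleaner than real autonomic responses.

## Known limitations and degenerate inputs

* Single-sample channels and already-standardized timelines are rejected;
  constant channels standardize to zero with a warning.
* Sub-second clock offsets between video and wristband are resolved by
  whole-second anchoring; there is no sub-second resynchronization.
* Timelines shorter than 4 s yield zero windows (not an error).
* A BiLSTM's per-step outputs are not constant on constant inputs (state
  accumulates over the 4 steps), so no time-invariance property is
  asserted for the recurrent fusion model; determinism and masking
  invariance are asserted instead.
* Inter-annotator reliability coefficients, spectral/HRV feature
  engineering, early/hybrid fusion and abstention outputs are explicit
  non-goals.

## Problem sizes used by the shipped experiments

The acceptance-level experiments run the recovery preset (12 × 600 s,
three seeds, plus one label-shuffled null) and the complementary preset
(9 × 400 s, three seeds, both schemes) at the full training schedules;
unit tests use cohorts of 4–6 subjects × 60–200 s with shortened
schedules. These sizes are the package's definition of its synthetic
studies and are stated here so results are reproducible exactly.
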