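---
title: "Methods: two-layer actigraphy screening for chronic insomnia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-layer actigraphy screening for chronic insomnia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the data model

Chronic insomnia (insomnia persisting beyond three months) is commonly
assessed with resource-intensive polysomnography or subjective
instruments. Wrist actigraphy offers a cheap, unobtrusive alternative:
an integer activity count per 60-second epoch, recorded at home over
about a week. `actiscreen` implements an automated pre-screening method
on such data.

The unit of analysis is one *night*: the vector of counts inside the
time-in-bed (TIB) interval, with TIB in minutes equal to the epoch
count. Segmentation into TIB is taken as given (in practice it comes
from the recorder's own rest-interval detection); the package neither
parses raw device exports nor detects lights-out, and files carry no
timestamps because no downstream computation uses clock time. Nights
shorter than 20 epochs are rejected: the sleep-onset rule needs a
10-minute window and the lag-based descriptors need several samples, so
20 provides a safe margin while discarding junk records. Gaps
(off-wrist epochs) are assumed absent; records with missing epochs are
rejected at the boundary rather than imputed.

A cohort pairs each subject with a group label, `CI` or `healthy`. The
validator enforces per-night and per-subject invariants everywhere; the
requirement of at least two subjects with both groups present is
enforced where cross-validation actually needs it (`ci_screen()` and
the LOSO layer), so single-subject cohorts remain usable for feature
extraction and summaries.

## Intensity filtering

Actigraphs score wake from counts above a sensitivity limit; typical
device limits are 20 (high sensitivity), 40 (medium) and 80 (low)
counts per epoch. The filter `apply_intensity_filter(x, L)` zeroes
every count *less than or equal to* L — boundary inclusive, which the
unit tests pin down explicitly — and leaves larger counts unchanged.
Level 0 is retained in the default bank (0, 20, 40, 80) even though it
is the identity on count data, preserving the 12 × 4 feature layout.
Three provable properties are tested on 1000 random nights: level-0
identity, idempotence, and monotone growth of the zeroed set with L.

## The 12 night features

On each filtered signal the package computes, in frozen order: `mean`,
`sd`, `SD1`, `SD2`, `ratio`, `CCM`, `SampEn`, `TST`, `SL`, `WASO`,
`SWR`, `SE`; names embed the level (`mean@InF20`), so alternative banks
remain well defined. All features are computed over the full TIB
signal, not merely post-onset epochs. Choices worth recording:

* **Variance conventions.** The `sd` feature uses the sample s.d.
  (denominator N−1). SD1/SD2 use population s.d. of the rotated
  coordinates ((x_{i+1} − x_i)/√2 and (x_{i+1} + x_i)/√2), which makes
  the identity SD1² + SD2² = Var(head) + Var(tail) exact; the test
  suite asserts it at 1e−9.
* **CCM.** The complex correlation measure is implemented as the mean
  *absolute* area of triangles spanned by consecutive lag-1 Poincaré
  points, normalised by C·n = π·SD1·SD2 and the number of triangles
  (N − 3). Published conventions differ on signed versus absolute
  areas; absolute areas were chosen so the measure is nonnegative,
  matching the positive group values reported for this kind of data.
  CCM = 0 when C·n = 0 (constant or collinear signals), and
  ratio = 0 when SD2 = 0.
* **Sample entropy.** SampEn(m, r) with m = 2 and r = 0.2 × sample
  s.d., the conventional physiological-signal defaults; neither value
  is standard for actigraphy specifically, so both are configurable.
  r is recomputed per filtered signal — filtering lowers the s.d., and
  with it the tolerance, which is consistent with entropy falling as
  filtering removes noise-like subtle movement. Matching counts use
  ordered pairs i ≠ j with i, j ≤ N − m (length m) and i, j ≤ N − m − 1
  (length m + 1), Chebyshev distance, self-matches excluded. Degenerate
  policies keep every feature finite: constant signal → 0; zero match
  count at either length → the cap ln((N−m−1)(N−m)), the −ln of the
  smallest representable nonzero conditional probability, flagged with
  an attribute. The Rcpp implementation is checked exactly against an
  independent `embed()`-based R oracle on random series.
* **Sleep parameters.** SO is the start of the first 10-minute run of
  zeros; SL = minutes before SO; TST counts zero epochs from SO
  *inclusive* ("starting from" the onset); WASO counts nonzero epochs
  after SO. When SO exists, SL + TST + WASO = TIB exactly (tested on
  1000 random nights); when it does not, the night is scored unslept
  (TST = WASO = 0, SL = TIB, SE = 0). TST and SE are nondecreasing and
  SL nonincreasing in the filter level — provable from the growing zero
  set — and the suite asserts exactly those three monotonicities. WASO
  is *not* monotone: in `c(20, 0×9, 100, 0×10)` the level-20 filter
  creates an earlier onset that exposes the surviving spike, raising
  WASO from 0 to 1; this counterexample is a regression test.
* **SWR orientation.** The ratio is defined as TST/WASO, and that is
  the default (`swr_orientation = "tst_over_waso"`), with the
  denominator floored at one minute so perfect nights stay finite. The
  scale of group values in published tables for this design, however,
  matches WASO/TST; the reciprocal convention is available as
  `"waso_over_tst"`. The default follows the printed definition; the
  switch is the escape hatch for the evident inconsistency.

## The two-layer model

Night-level labelling is deliberately blunt: every night of a CI
subject is "bad", every night of a healthy sleeper "good". This is
wrong for individual nights — both groups have atypical nights — but it
requires no diaries and retains the group signal in aggregate, which is
the point of the second layer.

**Layer 1** fits the classifier on all nights of N−1 subjects and
predicts the left-out subject's nights, for each subject in turn. The
random forest uses 100 trees, √p candidate features per split, and
unrestricted depth — "maximum depth equal to the training-set size" can
never bind, so it is implemented as unlimited growth. Trees are
scale-invariant, so standardisation defaults off for the forest and on
for the linear SVM (box constraint 1), where it uses training-fold
means and s.d.s only. The forest's bad-class probability (or the SVM
decision value through a logistic map) provides a night score in
[0, 1]. An optional inner stratified 10-fold CV over a user-supplied
grid (`mtry` or `cost`) exists because the surrounding protocol calls
for model selection; with the hyperparameters above fixed there is
nothing left to tune, so the default grid is empty and the fixed
configuration is used.

**Layer 2** sweeps Th = 1..(max nights): subject is CI iff its count of
predicted bad nights is ≥ Th (boundary inclusive). For each left-out
subject the threshold is learned from the out-of-fold predictions of
the other N−1 subjects only, then applied once. Ties in training
accuracy break toward the smallest Th: a pre-screening tool should
prefer catching cases (sensitivity) over specificity. The absolute
count is the canonical rule, so a subject monitored for fewer nights
than Th can only be screened healthy — a real limitation under
attrition, which is why a proportional variant
(`threshold_rule = "proportion"`) is provided for sensitivity analysis.
For ROC purposes the subject score is the bad-night fraction, the
natural graded version of the rule; ROC curves are emitted at both the
subject and night level since either view is informative.

Leakage is audited structurally: the fold membership attached to the
predictions must exclude the left-out subject, and each subject's
recorded threshold must re-derive exactly from the other subjects'
rows. Determinism is by construction — every fold seed derives from the
master seed by a fixed map — and is asserted by identical reruns.

## Evaluation machinery

Metrics are percent-scale sensitivity = 100·TP/(TP+FN), specificity =
100·TN/(TN+FP), accuracy = 100·(TP+TN)/total; an empty class yields NA
with a warning, never a silent zero. Per-feature statistics use the
Mann-Whitney U test (normal approximation with tie correction, the
right regime for tie-heavy count features; a feature constant across
all nights is scored p = 1 directly) and the midrank AUC, which equals
U/(n₁n₂) exactly — the suite checks both the U relation and a
pair-counting oracle. No multiple-testing correction is applied across
the 48 rows; the table is descriptive. The random-label control
permutes night labels (preserving balance) before retraining both
layers; an i.i.d. relabelling variant is behind `scheme = "iid"`. The
night ablation keeps each subject's *first* k nights — which nights to
keep is otherwise unspecified, and "first" matches how attrition
truncates real recordings.

## The synthetic cohort generator

`simulate_cohort()` defines the study conditions for all testing: 40
CI/healthy couples, 7 nights each, 60-second epochs, TIB ~ N(480, 30²)
minutes clipped to [360, 600]. Each night is an initial geometric wake
bout (latency; healthy mean 10 min, CI +5) followed by a two-state
per-minute Markov chain (healthy sleep→wake 0.045, wake→sleep 0.20; CI
+0.02/−0.05). Wake epochs emit rounded log-normal counts (healthy
location log 250, s.d. 0.6 on the log scale; CI location +log(310/250));
sleep epochs are zero with probability 0.95, otherwise a small
Poisson(2)+1 count representing subtle movement — it is exactly this
component that intensity filtering removes, reproducing the rise of
TST/SE and fall of WASO with the filter level. Subject random effects
(s.d. 0.15 on the emission location, 0.2 on logit rates) create
within-group heterogeneity, and with probability 0.15 a night is drawn
from the opposite group's regime — CI subjects get good nights and
healthy sleepers bad ones, which is what makes blanket night labelling
noisy and the second layer necessary. A single `effect_size` multiplier
scales all group offsets: 0 makes the groups identically distributed
(the null for chance-level checks), 1 is the default calibration, and 3
is used as the "strongly separated" regime in recovery tests. The
defaults were calibrated once so that unfiltered group mean activity
falls within ±30% of 69 (healthy) and 94 (CI) counts/epoch and the
TST/WASO/SE directions match the published pattern for couples cohorts;
they are not revisited per experiment. An optional attrition mode draws
each subject's night count from the empirical 1–7-night retention
profile of a week-long home protocol.

What the generator does *not* emulate: circadian shape within the
night, couple-level correlated awakenings (partners are independent;
a correlation knob would have no data-derived default), off-wrist
gaps, and device-specific count scaling. Passing tests therefore show
that the pipeline recovers group structure of the kind the method
assumes, not that it attains any particular accuracy on clinical data.

## Problem sizes and numerical choices in the test suite

Property tests use 1000 random nights for filter/sleep-parameter
invariants and 100 random series of length ≤ 200 for exact oracle
equivalence (SampEn, Poincaré identity at 1e−9, CCM, AUC). Recovery
uses the full 40-couple, 7-night design: five seeds at effect size 3
for the separable case (mean subject accuracy ≥ 90%), one null cohort
checked against the 95% binomial interval around 50% for 80 subjects,
20 label permutations for the control, and five seeds for the k = 3..7
ablation trend. End-to-end reproducibility is asserted byte-for-byte on
pipeline reruns with the same manifest.

## Limitations

The good/bad night labels are proxies, so night-level metrics
understate attainable per-night performance; the absolute-count
threshold penalises short recordings; SWR's printed definition and its
published group values disagree (both conventions are implemented); and
the CCM normalisation follows one of several conventions in the
literature. All synthetic results are conditional on the generator's
assumptions above.
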