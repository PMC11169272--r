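---
title: "Methods: stress-ECG fCAD prediction and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress-ECG fCAD prediction and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models, the
measurement chain, the synthetic data they are validated on, and the
numerical and design choices made where more than one reasonable option
existed. The companion README shows a worked example; the test suite and
`scripts/acceptance.R` compute every empirical number this package claims.

## The prediction problem

Functionally relevant coronary artery disease (fCAD) is CAD that causes
inducible ischaemia. The reference label comes from myocardial perfusion
imaging: with summed stress and rest scores SSS and SRS over 17 myocardial
segments, a summed difference score `SDS = SSS - SRS >= 2`, or a transient
ischaemic dilation ratio at or above the protocol threshold (1.22 dual
isotope, 1.12 single isotope), adjudicates fCAD. `adjudicate_fcad()`
implements exactly this rule, and the synthetic generator draws perfusion
scores so that every simulated patient satisfies it for their label —
making the rule assertable per record.

Three predictors are compared against a (simulated) cardiologist's
post-test probability:

* **clinical ensemble** — decision tree, random forest, logistic
  regression and SVM are cross-validated (stratified 5-fold, mean
  validation AUPRC) on exactly eight variables: age, weight, biological
  sex, height, resting heart rate, systolic and diastolic blood pressure,
  CAD history; the winner is refit on the full training data.
* **multi-task ECG network** — described below.
* **collaborative combiner** — a logistic regression on exactly three
  inputs (clinical-ensemble score, network score, cardiologist score),
  leveraging clinical judgement while letting the models correct its
  systematic biases.

## The 2-6-2 summary sequence

A full stress test is too long for a 1-D network at reasonable cost, so
each training instance is a 10 s summary: 2 s from the beginning of the
examination, a 6 s window sampled from the last 2 minutes of the stress
phase, and a 2 s window sampled from the last 3 minutes of recovery —
5000 samples at 500 Hz with internal boundaries at samples 1000 and 4000
(0-based, half-open). Up to 20 sequences per patient are built by
re-sampling the stress/recovery windows. Choices the construction had to
fix:

* window starts are drawn uniformly **without replacement on a 0.5 s
  grid** within the eligible ranges, so start times are unique and the
  draw is seeded;
* the pre-stress 2 s window is **fixed at the start of the recording**
  (only the stress and recovery windows re-sample);
* when fewer than 20 distinct placements exist, all distinct ones are
  emitted — there is no re-sampling with replacement;
* recordings without phase annotations get them from
  `estimate_stress_end()`: per-minute heart rate from detected R peaks,
  stress end at the end of the maximal minute, ties broken toward the
  earliest minute.

## ST-depression baseline

The non-ML comparator quantifies the classic ischaemia marker. Per
sub-segment of a 2-6-2 sequence: the isoelectric line is the mean over
valid beats of the mean of the last `l_PR` ms before the Q-wave onset; the
ST amplitude is the mean over valid beats of the **single sample 60 ms
after the J point** (a sample, not a window mean); depression is
isoelectric minus ST amplitude, so deeper ST below baseline is a larger
positive number. Deltas are taken against the pre-stress segment and
aggregated per patient by mean, median, min or max; `l_PR` (default 80 ms,
grid {40, 60, 80}), the aggregation, the delta type and the lead are
selected by validation AUPRC, separately per stress-type stratum, with
ties broken by first-in-grid order. Beats that span a 2-6-2 concatenation
boundary are flagged invalid — the joins are artefacts, not physiology.
Delineation is a derivative-threshold R-peak detector (200 ms refractory)
plus backward/forward slope-flattening searches for Q onset and J point;
the slope test runs on a 12 ms moving-average copy of the signal so
broadband noise cannot defeat the flatness criterion, while landmark
indices refer to the raw signal. The delineator sits behind a plain
interface (a tibble of per-beat fiducials with validity flags) so an
external delineator can replace it.

## The multi-task network

The ECG branch is a residual 1-D convolutional encoder: a stride-4 stem
convolution (kernel 17) followed by `n_residual_blocks` blocks, each a
stride-4 convolution + ReLU + stride-1 convolution (kernel 9) with a
subsampled identity skip, then global average pooling. The clinical branch
is a 2-layer feed-forward encoder of the eight standardised variables.
Their concatenation feeds four heads: fCAD (binary, the main task), SSS
and SRS (regressions on standardised scores), and pharmacological support
(binary). The loss is the weighted sum of per-task losses (binary
cross-entropy / mean squared error); auxiliary weights default to
`(sss, srs, pharm) = (0.5, 0.5, 0.25)` on a {0, 0.25, 0.5, 0.75, 1} grid
axis. The default architecture is deliberately desk-scale — 4 blocks, 16
channels — trained 2 epochs with Adam (batch 16); a full-depth encoder is
a configuration, not different code. The learning-rate grid is
{0.01, 0.001, 0.0001}. The selection grid over 12 single leads + 1
combined configuration x 3 preprocessing schemes x 3 learning rates
enumerates 117 configurations.

Three numerical choices in the network deserve explanation, because all
three were forced by the behaviour of null controls rather than by
headline accuracy:

* **zero-initialised heads** — the untrained network predicts a constant,
  so scores carry no accidental input tilt before any label has been seen;
* **layer normalisation of the pre-head representation** (per sample, no
  affine) — equalises feature magnitude across patients, preventing
  training dynamics from coupling the score to overall signal amplitude;
* **batch-mean centring of the normalised representation** — without it,
  heads accumulate a deterministic drift along `(base rate - 1/2) x
  E[features]`, which systematically tilts the scores of a model trained
  on label-free (permuted) data. At inference the stored training means
  are used; centring there shifts all logits equally and leaves rankings
  unchanged.

Per-patient scores are the arithmetic mean of the main-head probability
over the patient's sequences, which makes them invariant to sequence
order. Raw scores can be calibrated on the dedicated calibration split by
Platt scaling (default) or isotonic regression — both monotone, so AUROC
is untouched.

## Data splits

The held-out test set is the **last 25% of patients by enrolment order** —
a temporal split; in synthetic cohorts, generation order stands in for
enrolment date. The remaining development set is divided into 5 stratified
splits: validation is one fifth of development (so training-plus-
calibration : validation is 4:1), and the calibration set is a stratified
10% of the training portion. Prevalence is preserved across splits within
rounding.

## Evaluation

All method comparisons run on **paired bootstrap** draws: 25 draws of 80%
of patients, the same patient subset for every method in a draw (the
cardiologist scores each patient once, so pairing is what makes the
comparison fair). Metrics are AUROC (Mann-Whitney rank form), AUPRC
(average precision as a step integral, not trapezoidal) and the Brier
score. Net benefit at threshold probability `pt` counts `score >= pt` as
test-positive: `NB = TP/n - FP/n * pt/(1-pt)`; the decision curve carries
treat-all and treat-none references, and "imaging avoided per 100
patients" is the standard net-reduction-in-interventions transform
`(NB_model - NB_ref)(1-pt)/pt * 100` referenced to the comparator — the
transform itself is an interpretation choice, documented as such. Rule-out
tables use **strict `score < cutoff`** for the ruled-out fraction, report
NPV as missing when nobody falls below the cutoff, and attach bootstrap
95% CIs to the avoided fraction. Subgroup reports rerun the paired
bootstrap inside each stratum (skipping and flagging single-class strata),
and the interaction test is a two-sided Z on the between-stratum
difference of method-minus-reference AUROC gains using the bootstrap
standard deviations — the simplest statistic consistent with the bootstrap
machinery already in place. Distribution comparisons use the one-sided
Kolmogorov-Smirnov test or Welch's t-test with Bonferroni correction
(`min(1, m*p)`); 2x2 associations use Fisher's exact test with a
Woolf-logit CI on the cross-product odds ratio.

## The synthetic generator: what it emulates, and what it does not

Beats are sum-of-bump templates — Gaussian P and T waves, piecewise-linear
QRS — with exact fiducials; the segment between the J point and T onset is
shifted by the programmed ST offset relative to the PR level, so the
measurement chain has a hard oracle. The ST/T complex compresses with
shorter RR intervals (floored so the plateau always covers J+60 ms); the
PR interval does not, keeping the isoelectric window flat at any heart
rate. Recordings follow a heart-rate ramp (rest -> peak through the
stress phase, exponential recovery), with baseline wander (slow
sinusoids, default 50 µV), broadband noise (default 10 µV) and optional
movement bursts. Leads are amplitude-scaled variants of one source with
independent noise. Patients differ in beat morphology (amplitude/shape
coefficients of variation 0.15): real ECGs differ in voltage and wave
shape between patients, and without this variation the patient-level
feature space collapses onto the single programmed ST dimension, which
makes chance structure in any null experiment look like signal.

Label-conditional distributions: ischaemic patients draw stress-phase
depressions of 100-250 µV, non-ischaemic 0-50 µV (recovery offset is 0.4
of the stress offset); age, sex, blood pressure, resting heart rate and
CAD history shift modestly with the label (the CAD-history odds ratio is
parameterised at 2.64); perfusion scores are drawn on the SDS route (85%)
or the TID route (15%) for positives and below both criteria for
negatives. The simulated cardiologist score is a logistic squash of the
latent risk with logit-scale noise (sd 1.5) and a shrink-toward-0.5 tail
bias of 0.35 — a deliberately miscalibrated monotone readout emulating
systematic over/under-estimation of risk at the extremes. These defaults
are placeholders chosen for clinical plausibility, labelled as such in
`cohort_config()`.

What the generator does **not** model: physiologic 12-lead
vectorcardiography (leads are scaled copies), arrhythmia, per-lead
morphology differences, and any imaging content (perfusion scores are
drawn, not derived from images). Passing tests therefore demonstrate that
the measurement chain, training loop and evaluation machinery are correct
and faithful to their definitions — not that the models would reach any
particular accuracy on clinical data, where the coupling between ST
depression and fCAD is far weaker than the generator's.

## Null-control design

The permuted-label control deserves its own note. At desk scale (around
120 training patients), the empirical correlation between a permuted and
the true label vector has standard deviation of roughly `1/sqrt(n)`, about
0.09 — and a model that generalises almost perfectly along the programmed
ST dimension amplifies that chance correlation into held-out AUROC
deviations of ±0.2. A single permuted run is therefore not a meaningful
null at this problem size. The control used in the acceptance tests and
the acceptance script is the **mean over independent permutation
replicates** (fresh shuffle and training seed each); permutations reassign
each patient's full target tuple — label, SSS, SRS, pharmacological
support — jointly, because permuting the label alone leaves the shared
trunk trainable from the untouched auxiliary targets.

## Numerical choices

* All filters are applied forward-backward (zero phase), so fiducial
  times survive preprocessing; R-peak shift on clean signals stays under
  4 ms. Signals are demeaned before high-pass filtering to avoid DC-step
  edge ringing.
* The "thorough" scheme's 0.05-150 Hz band is implemented as an order-3
  high-pass plus order-5 low-pass cascade: a single order-5 transfer-
  function band-pass with a normalised lower edge of 2e-4 is numerically
  unstable under `filtfilt`. Windows: moving average 15 ms, moving median
  600 ms, Savitzky-Golay 25 ms / order 3, winsorizing at the 0.1/99.9
  percentiles — all exposed in `apply_scheme()`.
* The learning-rate grid is implemented as {0.01, 0.001, 0.0001}; the
  duplicated middle value in the source grid is treated as a typo.
* Degenerate inputs fail loudly and early: single-class training data,
  empty calibration classes, sequences with a beat-free phase, phases too
  short for the 2-6-2 windows. Collinear or constant combiner inputs fall
  back to a reduced / intercept-only fit, flagged on the model object.
* Every stochastic step — cohort generation, window sampling, fold
  assignment, initialisation, batch order, bootstrap draws — flows from an
  explicit integer seed, and identical configurations reproduce results
  bit-identically.

## Problem sizes

The shipped defaults are deliberately small so that a complete run —
generator to decision curves — finishes in minutes on one CPU core: the
acceptance checks use a 50-patient noiseless cohort for ST recovery, a
200-patient cohort (8 sequences/patient) for label recovery with the
4-block/16-channel network, and 36-60-patient cohorts for the remaining
suites. These sizes are the package's validation design, chosen to make
the oracles sharp; nothing in the code ties the models to them.

## Known limitations

* The synthetic leads are amplitude-scaled copies; per-lead selection
  logic is exercised structurally, not physiologically.
* The attribution estimator is permutation sampling over feature groups;
  it is additive by construction but, with few permutations, individual
  group values are noisy. The backend is pluggable behind the additive
  contract.
* The grid-search drivers (`grid_search_mtl()`, `select_st_params()`) are
  written for correctness, not throughput; full-size grids (5x5x5x3) are
  feasible but slow in R at realistic cohort sizes.
* Dynamic-time-warping alignment of extracted salient waves is left to
  downstream tooling; the package extracts and tags the waves.
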