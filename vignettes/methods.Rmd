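---
title: "Methods: simulating, balancing and scoring hemodialysis sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, balancing and scoring hemodialysis sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialrisk)
```

## The problem

Patients on maintenance hemodialysis — three sessions a week, up to 240
minutes each — are prone to intradialytic hypotension: a fall of systolic
blood pressure (SBP) of more than 20 mmHg, or of mean pressure by 10 mmHg,
accompanied by nausea, cramps or dizziness. For hemodynamically stable
patients dialysing at home, an automatic early warning from cheaply
measurable vitals (SBP, DBP, heart rate, weight, sampled every 30 minutes
at timepoints T0..T8) lets remote staff intervene before a crisis.

`dialrisk` implements a two-stage alerting pipeline: a first Random Forest
(stage `rf1`) scores the session one hour in, a second (`rf2`) three hours
in, targeting crises in the final treatment hour; their scores are averaged
into a fused alarm score. Because symptomatic sessions are rare (17 of 200
in the reference cohort), training sets are rebalanced by generating
synthetic minority sessions with correlated Gaussian noise, and the whole
pipeline is validated by leave-one-out cross-validation (LOOCV) with
ROC/AUC, Hanley–McNeil standard errors and Youden-index operating cutoffs.

## The synthetic cohort as a stated world

The clinical dataset behind the reference statistics was never deposited,
so the package ships a generator whose defaults *are* those statistics:

* **10 patients, 20 sessions each** (200 sessions); 17 symptomatic
  sessions allocated to specific patients (0, 3, 5, 6, 2, 0, 0, 0, 1, 0)
  as a hard constraint, 14 of 17 with last-hour onset (T7/T8), the other
  3 with onset uniform on T1..T6.
* **Per-patient marginals**: each patient's across-session-and-timepoint
  mean and SD of weight, SBP, DBP, HR.
* **Class shifts**: per-timepoint symptomatic-minus-asymptomatic mean
  differences for SBP and DBP (negative — symptomatic sessions run
  hypotensive, increasingly so late in the session). No HR shift is
  applied: none was detectable in the source data.
* **Correlation targets**, induced per class on standardised draws:
  weight–SBP/DBP/HR and SBP–DBP at each timepoint, a 0.99 correlation
  between start weight and every later weight, 0.99 between start weight
  and the prescribed end-of-session target weight, and 0.48 between the
  interdialytic weight gain and the prescribed hourly weight loss. The
  SBP–DBP coupling was only published for symptomatic sessions and is
  reused for both classes.

The 36-variable per-class target matrix is assembled from an explicit
latent-factor loading (`vitals_corr_matrix()`): a shared weight factor
carries the 0.99 autocorrelation, per-timepoint residuals carry the
weight–vital and SBP–DBP couplings. Built as `L %*% t(L)`, the matrix
reproduces every stated pairwise target exactly and is positive
semi-definite by construction; unspecified cross-timepoint correlations
fall out of the factor structure rather than being set to zero (which
would make the matrix indefinite).

Quantities the correlation analysis does not pin down were fixed once at
physiologically typical values and are configurable
(`session_marginals_default()`): interdialytic gain ~ N(2, 0.5²) kg,
hourly weight loss 0.5 ± 0.1 kg/h (floored at 0.1), dry weight 2 kg below
the patient's mean weight. Weight falls linearly by half the hourly loss
per 30-minute step; the stochastic part of the weight SD is deflated so
the profile SD describes the *total* across-grid dispersion, trend
included. `prev_end_weight` (the previous session's final weight, the
numerator of the interdialytic gain) is drawn per session as
`weight_t0 - gain`, not chained to the literally preceding simulated
record: chaining would turn per-patient weight into a random walk and
break the stationary marginals. The gain–hourly-loss coupling is induced
on the dry-weight-normalised gain, the quantity the 0.48 target refers to.

**What a green test does not establish.** The generator emulates moments,
shifts and pairwise correlations — not intra-session hemodynamics, plasma
refilling, ultrafiltration physics, medication effects or measurement
error. Classifier performance on this cohort shows the pipeline works and
is calibrated to the reference statistics' effect sizes; it is not a
clinical validation. Note also that symptomatic sessions belong to 5
specific patients, so part of the separability is patient composition —
exactly as in the source cohort.

## Engineered features

* **Interdialytic weight gain** `(weight_t0 - prev_end_weight) /
  dry_weight`: excessive interdialytic fluid gain forces fast removal and
  predisposes to hypotension. Dimensionless; may be negative.
* **Critical indicator** of an SBP drop: 1 when current SBP <= 90 mmHg,
  0 when >= 100, linear in between — but identically 0 for sessions whose
  *initial* SBP is not above 100 mmHg, for which a low absolute pressure
  is baseline rather than a drop. The boundary case (initial SBP exactly
  100) is suppressed, consistent with flagging only sessions that start
  *above* 100.

Each stage sees 13 features: the four vitals at T0 and at the stage's
late timepoint (T2 / T6), hourly weight loss, target end weight, the
interdialytic gain, and the critical indicators at the stage's last two
timepoints (T1/T2 for `rf1`; T5/T6 for `rf2` — the source describes only
"the same parameters after 180 minutes", so the indicator timepoints
mirror the first stage's last-two-available convention). The target end
weight and hourly loss are 0.99-correlated readings of the same
prescription; both are kept since the source conflates them. Labels use
the study's encoding (0 = symptomatic). `rf2` labels 0 only last-hour
onsets; earlier-onset sessions are *relabelled* 1, not dropped — by the
second warning their crisis is past, and dropping them would leak onset
information into the training-set composition.

## Balancing by correlated Gaussian noise

With 183 nonsymptomatic vs 17 symptomatic sessions, undersampling would
leave ~30 usable observations, so the minority class is oversampled:

1. screen each variable for normality (one-sample Kolmogorov–Smirnov at
   1%, advisory: failures warn, never abort — skipped below 5
   observations where the test is undefined);
2. draw independent standard normals;
3. induce the estimated correlation structure. For two variables this is
   `u' = u*sqrt(1 - rho^2) + v*rho, v' = v`; for the full 40-variable
   session vector it is the triangular (Cholesky) generalisation in a
   fixed canonical variable order (weights, SBPs, DBPs, HRs by timepoint,
   then prescription fields), which reduces exactly to the pairwise rule
   for two variables. A 17-row estimate of a 40x40 correlation matrix is
   rank-deficient, so it is repaired by eigenvalue clipping at 1e-6 and
   renormalisation to unit diagonal;
4. restore native units as `mu + k*sigma*z`. The factor `k` scales the
   synthetic spread; `k = 1` (the default) reproduces the estimating
   sample's SDs, and a sweep utility re-runs the evaluation across `k`
   to show the AUC is insensitive to it.

Synthetic sessions inherit onset timepoints resampled from the
estimating sample, are flagged `is_synthetic`, and are never scored.

## Classification and validation

The Random Forest is implemented in compiled code (no forest
implementation is assumed at runtime): bootstrap-bagged CART trees, Gini
splitting, `floor(sqrt(13)) = 3` candidate features per node, grown to
purity (`min_leaf = 1`), 500 trees by default; a session's score is the
fraction of trees voting symptomatic, and leaf ties vote symptomatic
(alarm-favouring). A dedicated xorshift RNG makes training
byte-reproducible for a given seed across platforms.

Validation is leave-one-out: for each real session, the oversampler is
re-fit on the *remaining* symptomatic sessions and the two forests are
retrained on the rebalanced remainder; the held-out session is scored by
both and the fused score is their mean. The source does not state whether
its 166 synthetic sessions were generated once (before splitting) or per
fold; generating per fold is the leakage-free choice and is asserted per
fold (the held-out id may appear in neither the training ids nor the
oversampler's estimation sample). One measured consequence, documented by
the null-world test: when the two classes are identically distributed the
fused LOOCV AUC sits *below* 0.5 (~0.34), because each held-out positive
lies outside the tight synthetic cloud re-estimated from the other 16 —
a pessimistic, never optimistic, bias.

Folds that would empty a stage's training class or leave fewer than 3
symptomatic sessions (the oversampler's minimum) are skipped with a
warning.

## Evaluation

The ROC sweeps every distinct score as a threshold (symptomatic predicted
iff score >= threshold; ties toward alarm). The trapezoidal AUC equals
the Mann–Whitney probability of correctly ranking a random
positive/negative pair with ties counted one half — property-tested
against a brute-force oracle. Its standard error uses the Hanley–McNeil
closed form (`Q1 = A/(2-A)`, `Q2 = 2A²/(1+A)`); the source prints "±0.05"
without naming a formula, Hanley–McNeil is the standard choice and a
bootstrap SE is provided as a cross-check. AUCs are compared with an
unpaired z-test (the paired variant needs per-session pairing information
the source does not give). The operating cutoff maximises the Youden
index, computed on integer TP/FP counts so exact ties break
deterministically toward the higher threshold (fewer alarms).

## Numerical and degenerate-case choices

* Seeds: every random draw descends from a single integer seed through a
  counter-based derivation, so adding a pipeline stage never perturbs an
  earlier stage's stream.
* The printed 8.8% symptomatic rate is inconsistent with the printed
  counts (17/200 = 8.5%); the counts are authoritative since the
  balancing arithmetic (183 - 17 = 166) depends on them.
* Constant columns in the oversampler's estimating sample keep their
  constant value and contribute zero correlation.
* Jointly infeasible correlation triples (weight–SBP, weight–DBP,
  SBP–DBP) are clamped with a warning; the defaults are feasible.
* Missing non-T0 vitals are imputed by last observation carried forward;
  a missing T0 is an error.

## Known limitations

* No intra-session autocorrelation dynamics beyond the linear weight
  trend; pressures at different timepoints correlate only through the
  shared weight factor.
* The third class of nonsymptomatic hypotensive events, per-patient
  personalised models, and the telemonitoring platform itself are out of
  scope.
* Headline clinical performance numbers (AUC ≈ 0.76/0.73 etc.) were
  computed on the undeposited clinical data; on the synthetic default
  cohort the pipeline produces numbers of the same order, but they are
  properties of the stated world, not reproductions.
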