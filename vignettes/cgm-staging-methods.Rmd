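---
title: "Methods: CGM metrics, staging and progression prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CGM metrics, staging and progression prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Children with two or more confirmed islet autoantibodies have presymptomatic
type 1 diabetes and are staged by venous glycemia: stage 1 (normoglycemia),
stage 2 (dysglycemia) and stage 3 (clinical diabetes), using the oral glucose
tolerance test (OGTT) and HbA1c. The OGTT is burdensome in young children.
Blinded continuous glucose monitoring (CGM) is an attractive alternative:
a 10-day wear yields a dense glucose series from which glycemic exposure and
variability summaries can be computed without venous sampling. This package
implements that analysis chain — CGM quality control, the per-trace metric
suite, consensus OGTT/HbA1c staging, control-anchored threshold classifiers,
a composite logistic Progression Prediction Score (PPS), and time-to-event
evaluation — together with a synthetic cohort generator so the whole pipeline
is testable end to end without access to any clinical data set.

## Quality control

Sensor readings are unreliable immediately after insertion, so the first
12 hours of every wear are discarded (half-open: a sample exactly 12 h after
the first is retained). Implausible readings are then flagged by three
configurable detectors:

* **flat-line**: runs of identical consecutive values lasting ≥ 3 h — a live
  sensor at 5-minute cadence essentially never repeats one value for hours;
* **jump**: adjacent-sample rate of change above 15 mg/dL per minute, both
  endpoints flagged;
* **rail-pinning**: ≥ 30 min pinned at the 40 or 400 mg/dL reporting limits.

These detectors are this package's own design; published cleaning procedures
for blinded pediatric CGM describe removal of implausible stretches without a
portable algorithmic definition, so the rules here are explicit stand-ins
with tested defaults rather than a reproduction of any specific study's
filter. Flagged samples are dropped; a trace is included only if strictly
more than 96 hours of samples remain (retained sample count × nominal
cadence — recording gaps do not count as wear) and less than 20 % of the
trimmed trace was flagged (traces above that are excluded outright as
bulk-implausible). The 96-hour bound is exclusive; the boundary is tested.

## The metric suite

For each included trace: mean glucose, SD, CV (100·SD/mean), maximum,
percentage of time above 140/160/180/200 mg/dL (TA140 …), percentage below
80/100 mg/dL (TB80, TB100), and the mean glucose between 03:00 and 06:00
local clock time. Conventions, fixed and documented because they change
numbers at the margins:

* threshold comparisons are strict (`>` for TA, `<` for TB), so a sample at
  exactly 140 mg/dL does not count as "above 140";
* time percentages are sample-count proportions — after QC the cadence is
  uniform, so counting samples equals integrating time, and no trapezoidal
  weighting is applied;
* SD uses the population denominator *n*; with thousands of samples per wear
  the difference from *n − 1* is far below reporting precision, but the
  convention is fixed;
* the nocturnal window is half-open [03:00, 06:00) in local clock time,
  pooled across nights (a flag switches to per-night means; pooling weights
  nights by their retained samples);
* all computation is in mg/dL; mmol/L is a display conversion (÷ 18.016,
  one decimal) only.

The additive-shift identity is the analytic backbone of the sensor-error
reasoning: adding a constant *c* to every reading moves the mean and maximum
by exactly *c*, leaves SD unchanged, makes every TA percentage
non-decreasing and every TB non-increasing, and lowers CV for *c* > 0. A
between-sensor *additive* offset therefore inflates mean, nocturnal mean and
TA metrics while leaving SD (and essentially CV) alone — which is exactly
the fingerprint probed by correlating the nocturnal mean with TA140, SD and
CV across healthy controls.

## Staging rules

Staging from autoantibody count, the OGTT panel and HbA1c follows the
consensus bands; fewer than two confirmed autoantibodies means control
regardless of glycemia. Rules are evaluated most-advanced first so overlaps
(a 120-min glucose of 200 satisfies both a stage-2 and a stage-3 reading)
resolve upward. Stage 3 here is *provisional*: a clinical diagnosis requires
confirmatory repeat testing, which is a workflow, not a computation. The
published bands leave two narrow numeric gaps — fasting glucose in
(125, 126) mg/dL and HbA1c in (6.4, 6.5] % — that belong to neither the
stage-2 band as printed nor the stage-3 cutoffs. We read the dysglycemia
bands as "≥ lower bound up to the stage-3 cutoff", label such values
stage 2, and mark the fired criterion `"range_gap"` so the cases are visible
to the analyst. HbA1c of exactly 6.5 % is stage 2, because the stage-3
criterion is strictly greater than 6.5. An exhaustive grid over all boundary
values is part of the test suite.

## Threshold classifiers and the PPS

The discriminating parameters are glucose SD, TA140, TA160 and TA180. For
each, the **100 %-specificity threshold** is the maximum of the metric over
the control traces; a case is flagged only when *strictly* above the cutoff,
so no derivation control is ever flagged and specificity on those controls is
1.0 by construction. Cutoffs are kept exact; rounding (one decimal) is for
display. The combined classifier is the **any-k rule** (default k = 2):
positive when at least two of the four metrics are elevated.

The **Progression Prediction Score** is a maximum-likelihood logistic
regression of progression-within-one-year on the four metrics in natural
units (no standardization — coefficients are per mg/dL or per percentage
point). Participants censored before the horizon without an event are
indeterminate and excluded from the fit; autoantibody-negative controls never
enter it. With few events the likelihood can separate; the fit then falls
back to a small ridge penalty (10⁻³ per squared non-intercept coefficient,
unpenalized intercept) and records that in the diagnostics instead of
returning divergent coefficients. Scores are banded at the published
boundaries: low < 0.19, mid 0.19–0.4 (both ends inclusive), high > 0.4.
The score is descriptive, fit in-sample; no cross-validation machinery is
provided because the published score itself is explicitly not validated.

## Evaluation statistics

* **ROC/AUC** — the AUC is computed as the Mann–Whitney U statistic divided
  by n₁·n₂ with midrank tie handling, with a DeLong placement-value
  confidence interval. The implementation is exercised against an exhaustive
  pair-counting oracle on all tie-rich datasets up to n = 5 and against
  `pROC` as an independent reference.
* **Kaplan–Meier** — product-limit estimate via the `survival` package with
  Greenwood standard errors; one-year cumulative risk is 1 − S(1) with a
  linear ("plain") confidence interval clipped to [0, 100] %. Group contrasts
  use the log-rank test.
* **Group comparisons** — median (IQR) per group, Kruskal–Wallis across
  groups, pairwise Mann–Whitney (normal approximation, no multiplicity
  correction, matching the descriptive use); categorical variables use the
  chi-square test, switching to Fisher's exact test when any expected cell
  count is below 5 (the choice rule is a documented heuristic).
* **Offset correlations** — Pearson by default (a flag switches to
  Spearman) between the nocturnal mean and TA140/SD/CV.
* **Repeatability** — for participants with two QC-passed wears:
  second-minus-first differences per metric, per-threshold flag concordance,
  any-k concordance, and the fraction with |Δ mean| > 10 mg/dL.
* Report percentages round half-up to integers (base R rounds half-even,
  which would turn 9/11 = 81.8 % into 82 either way, but 0.5 cases differ).

## The synthetic cohort generator

No public data accompany studies of this design, so the generator is a
first-class, tested module that defines the conditions under which the
pipeline is exercised. Each participant has a latent state: a fasting-level
baseline (mg/dL) and a dimensionless excursion scale multiplying meal
excursions. A reading at time *t* is

```
clip(baseline + circadian(t) + Σ meal_pulses(t) + AR1(t)
     + session_offset + white_noise, 40, 400)
```

* **Circadian term**: a single 4 mg/dL sinusoid peaking at 18:00, so the
  03:00–06:00 window sits near the trough, approximating fasting levels. No
  published diurnal model exists for this population; one sinusoid is the
  minimal shape with the right phase.
* **Meals**: Poisson times (3.2/day) restricted to 06:00–22:00, each a
  gamma-shaped pulse peaking 45 min after onset with amplitude
  N(31, 10) × excursion scale (mg/dL, truncated at 0). This is the minimal
  mechanism producing stage-dependent TA and SD differences.
* **Physiologic noise**: AR(1) at the 5-minute cadence with lag-1
  correlation 0.9 and innovation SD 2.5 mg/dL.
* **Sensor error**: one additive offset per wear session, N(0, 8) mg/dL,
  plus white within-session noise (SD 2). The offset is additive, not
  multiplicative — the error mode consistent with factory-calibrated
  sensors reading consistently high or low for a whole wear. No
  multiplicative term is included by default.
* **Clipping** at 40/400 mg/dL mirrors commercial reporting limits.

Group defaults (33/46/18 controls/stage 1/stage 2; baselines 107/109/120
mg/dL with 5 mg/dL between-participant SD; excursion scales 1/1.2/1.85)
were chosen once, analytically, so the generated metric distributions take
the values reported for such cohorts: control median mean glucose ≈ 115
mg/dL with SD ≈ 16 and CV ≈ 14 %, rising to ≈ 136/26/19 in stage 2, with
TA140 ordering control < stage 1 < stage 2. Between-participant
heterogeneity log-links the excursion scale to the baseline (coefficient
0.19 per standardized baseline deviation, plus 0.10 log-SD jitter): children
with higher overall glycemia are also more variable. That link is what
reproduces the observed additive-offset fingerprint — a strong
nocturnal-mean/TA140 correlation (≈ 0.85), a moderate positive
nocturnal-mean/SD correlation, and a near-zero nocturnal-mean/CV
correlation; without it, CV = SD/mean would correlate spuriously and
negatively with the nocturnal mean.

OGTT panels and HbA1c are drawn from group-dependent normal distributions
whose targets make the consensus rules reproduce the intended arm for the
large majority of draws while leaving realistic label noise; an individual's
excursion scale shifts the 120-min glucose (15 mg/dL per unit) and HbA1c
(0.15 % per unit) upward. These links are generator conveniences, not
claimed physiology, and downstream analyses always use the *realized* stage
labels. Progression times are exponential (0/0.07/0.58 events per year for
control/stage 1/stage 2 — about 7 %/44 % one-year progression in
stage 1/stage 2) with administrative censoring at 1.5 years. A configurable
number of participants (default 18, from the autoantibody-positive groups)
receives a second wear about 6 months later with a freshly drawn sensor
offset.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: hypoglycemic excursions are rare (TB80 is
essentially zero, whereas real cohorts show small positive values);
meal sizes, timing and composition effects are idealized; sensor noise is
stationary within a session (no drift, compression lows, or dropout gaps);
and progression hazards are constant within group rather than linked to the
individual's glycemia beyond group membership. Conclusions about classifier
*mechanics* (specificity by construction, additive-offset behavior,
estimator correctness) transfer; cohort-specific magnitudes do not.

## Numerical and design choices

* Seed handling: a single cohort seed fans out to per-participant and
  per-trace substreams drawn up front, so adding a downstream stage does not
  shift earlier randomness; identical config + seed reproduce artifacts
  byte-for-byte.
* All analysis stages are deterministic; randomness lives only in the
  generator and in nothing else.
* Degenerate inputs fail loudly: empty traces, traces with no nocturnal
  samples, single-class outcomes, cohorts without controls, and scores
  outside [0, 1] raise errors rather than returning silent zeros.
* Ties in the ROC use midranks; the exhaustive small-sample suite covers
  every tie pattern up to n = 5.
* Problem sizes in the test and acceptance runs (e.g. 100-trace metric
  oracles, a 200-participant paired-wear cohort, 100 refit replicates at
  n = 2000) are chosen to make Monte-Carlo error small relative to the
  tolerances tested while keeping a default run in the minutes range on one
  core.

## Limitations

The implausibility detectors are stand-ins, not a validated reproduction of
any study's cleaning procedure. The staging gap handling (range-gap values
to stage 2) is an explicit reading of ambiguous published bands. The PPS is
an in-sample descriptive score. And because the study data behind the
motivating analysis are not public, the package's cohort-level numbers are
properties of the synthetic generator, not of any clinical cohort.
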