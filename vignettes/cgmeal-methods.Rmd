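---
title: "cgmeal: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cgmeal: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmeal)
```

This vignette documents the models behind `cgmeal`, the tunable parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical and design decisions taken where the method left room.

## 1. The measurement problem

Free-living multimodal studies record interstitial glucose every 15
minutes, hip-accelerometer steps every minute, and self-reported food logs.
Self-report timing is unreliable: items arrive in stages, late, or as an
end-of-day batch, and some meals are never logged. The pipeline therefore
treats *annotator-corrected timings* — several independent readers placing
each log at the start of a bell-shaped CGM excursion, or tagging it
unknown — as the timing source, and reconciles them algorithmically.

## 2. Meal-event segmentation

**Log merging.** Item rows logged at the same minute under one
meal-occasion label form a log; logs with the same label within 60 min
merge into one meal log timed at the *first* constituent. Merging is
greedy and anchored at each group's first log: a log at minutes 0 and 59
and another at 90 yields groups {0, 59} and {90}. A chained convention
(anchor moves to the latest member) would merge all three; the anchored
form is used because the merged time is defined as the first log's time,
which makes the 60-min window a bound on staging duration rather than on
inter-log gaps.

**Aggregation.** Per participant-day, non-unknown annotated timings are
clustered by 1-D DBSCAN on hours-since-midnight, `eps = 1.5`,
`min_samples = 2`: every group holds at least two timings, groups are at
least 1.5 h apart, and DBSCAN noise points (singletons) are discarded.
Distances are plain absolute differences within one day; days are processed
independently, so a cluster cannot straddle midnight (annotations are
bounded at 04:00–23:59 anyway).

**Start-time selection.** The group's start time is the member timing with
the largest `MGR_3h`. Two numerical rules matter:

* *Ties* break to the earliest timing. On a 15-min grid, timings a few
  minutes apart often see identical sample sets, so ties are common; the
  earliest choice is deterministic and favours excursion onset.
* *Partial coverage*: a candidate needs a baseline sample within one
  nominal interval of its timing and at least 50% of the expected 3-h
  samples; otherwise it is skipped, and a group with no covered member is
  discarded with a diagnostic.

**Qualification.** An event requires a maximum rise of ≥ 18.6 mg/dL over
the 3-h segment relative to the baseline *at the start time* (not the
segment minimum — consistent with the iAUC baseline), inclusive at the
boundary (with a 1e-9 epsilon against floating-point representation). The
event links to the merged log referenced by the majority of its corrected
timings (ties → unlinked) and is *high-agreement* when ≥ 3 distinct
annotators' corrected timings for that log fall in the group.

**Agreement.** `intraclass_correlation()` is ICC(2,1) — two-way
random-effects, absolute agreement, single measurement — computed on
complete logs-by-annotators matrices only.

## 3. Meal biomarkers and the elevated/normal classification

`MGR_3h` follows the fixed order: segment → subtract baseline → clip
negatives → trapezoid over minutes. No zero-crossing refinement is applied
between samples; on a 15-min grid the clipping step can mis-assign at most
one sample-width of area, which is why the package's accuracy contract is
agreement within 2% with a 1-min oracle on smooth excursions (exact on
piecewise-linear traces sampled at their nodes).

The classification maps a single meal's response through a cohort-level
("population") robust regression of HbA1c on each participant's *mean*
`MGR_3h` — averaging smooths out food/activity idiosyncrasies and aligns
with HbA1c being itself an average. The fit is a Huber M-estimate
(tuning constant 1.345, the standard 95%-efficiency default; the method
only names "robust regression") of degree 1, with a quadratic term as a
sensitivity option; monotonicity over the observed range is asserted and a
violation (possible for degree 2) warns. A meal is **elevated** when its
mapped hypothetical HbA1c reaches 5.7% (at-risk/prediabetes) or 6.5% (T2D),
boundary inclusive. Events without a linked calorie log are classifiable
(only `MGR_3h` is needed) but excluded from calorie-adjusted causal
analyses.

## 4. Daily records

The analysis window starts at the earlier of (first meal start, first wear
minute after 04:00) and ends at the later of (last meal start + 3 h, last
wear minute before 23:59), clipped to 04:00–23:59; the 23:59 bound
dominates the +3 h rule, treating both ends symmetrically. Wear time uses
an explicit mask when present, else non-wear is detected as runs of ≥ 90
consecutive zero-step minutes — a deliberate simplification of actigraphy
wear algorithms (no spike tolerance), which is why external masks take
precedence. Exclusions (each recorded, days never silently dropped): no
meal events; wear < 10 h (inclusive at exactly 10 h); first/last study day
(incomplete CGM); any sample ≤ 40 or ≥ 500 mg/dL (sensor limits). TIR uses
observed CGM samples in the window as denominator so gaps do not deflate
it; the lower bound is 54 mg/dL with 70 as a sensitivity option. Events are
assigned to days by start time; a meal starting before the window end
contributes wholly to that day (the window already extends 3 h past the
last meal). Adherence: a food-logging day needs ≥ 2 merged meal logs, a CGM
day the full expected sample count, an accelerometer day ≥ 10 h wear;
cohort feasibility requires ≥ 50% of participants with ≥ 10 simultaneous
days.

## 5. Causal analysis

For a treatment `T` with covariates `X`, the generalized propensity score
is `e_i = P(T_i = t | X_i)` and weights are `w_i = 1/e_i`.

* **Continuous T** (daily steps, post-meal steps, calories; analysed per
  1000 steps / 100 kcal): a linear mixed propensity model
  `T ~ X + (1 | participant)`; the density is Normal with the model's
  *conditional* predictions (random intercepts included) and residual SD.
  The marginal-prediction alternative was tested and rejected: when
  treatment and a covariate share a participant-level effect, marginal
  predictions leave systematic weighted correlation behind, while
  conditional weights balance both the covariates and the shared effect.
* **Categorical T** (elevated count, reference category 0, contrasts 0→1,
  0→2, 0→≥3): the multinomial mixed propensity is implemented as
  one-vs-rest random-intercept logistic models with probabilities
  normalized across categories (a multinomial mixed-logit package is not
  among the dependencies); fixed-effects logistic fallback on failure,
  with a warning.
* **Stabilization and truncation.** Weights are stabilized by the marginal
  density/category share and truncated at the 1st/99th weight percentiles
  by default; the method statement gives unstabilized `1/P`, but weight
  explosion must be handled, so both options are exposed and reported
  (truncation counts are attached to the weights, never silent).
* **Balance.** Continuous: weighted Pearson |r| < 0.1 per covariate;
  categorical: maximum pairwise weighted SMD < 0.2. Factor covariates are
  ordinal-coded (one statistic per study covariate, matching how the
  balance tables treat "the covariates"); zero-variance covariates are
  excluded with a note.
* **Outcome models.** Weighted mixed-effects regression with a random
  intercept per participant; linear for TIR/mean glucose/`MGR_3h`
  (t statistics), logistic for the elevated indicator (z statistics, odds
  ratios reported). The covariate set is added (doubly robust) whenever the
  balance report fails any covariate, and always includable by
  configuration. Significance convention: p < 0.01, no multiplicity
  adjustment.
* **Standard errors.** Unweighted fits use model-based errors, so unit
  weights reproduce the ordinary mixed fit exactly. For *weighted linear*
  fits the default is a cluster-robust GLS sandwich (exact for the
  block-diagonal random-intercept covariance, df = participants − 1):
  model-based errors treat IPW weights as precision weights and were
  measurably anti-conservative in simulation (empirical size ≈ 0.045 at
  nominal 0.01; the sandwich restores 0.010). `se_type = "model"` recovers
  the naive behaviour.
* **The four study analyses** (`run_study_analyses()`): (a) elevated count →
  TIR and mean glucose, covariates {baseline glucose, duration, daily
  steps}; (b) daily steps → same outcomes, covariates {baseline glucose,
  elevated count, duration}; (c) post-meal steps → `MGR_3h` and
  elevated-odds, covariate {calories}; (d) calories → same, covariate
  {post-meal steps}. Meal-level rows are restricted to high-agreement
  events with non-zero calories and a recorded post-meal step count, and
  IPW is skipped when |cor(T, covariate)| < 0.1 (the adequate-balance
  shortcut), falling back to covariate-adjusted mixed regression.

## 6. What the synthetic generator states — and what it does not

`simulate_cohort()` states a world in which the pipeline's assumptions hold
exactly: a flat participant baseline (small diurnal sine + AR(1) sensor
noise), one log-normal-shaped bell per meal (sharp rise at ~45 min, slow
decay — not a symmetric Gaussian) whose continuous-curve incremental area
*is* the planted `MGR_3h`; per-meal responses
`base + 3.0·kcal − 0.641·(post-meal steps) + noise`; participant HbA1c
`4.6 + 4e-4 · mean MGR + N(0, 0.3)` with status from standard bands; wear
roughly 06:30–22:30 with occasional low-wear days; sensor placement at
10:00 on day 1 and removal at 14:00 on the last day (so first/last days are
incomplete by construction); and a logging-error model (10% missing, mean
15-min exponential delay, 5% batch-logged days, staged items). Annotators
apply Normal jitter (default SD 5 min), tag 5% unknown (always for
batch-logged snacks, which cannot be placed), and detect 80% of unlogged
meals.

Defaults were chosen once to land near a 36 × 14 study's magnitudes
(~1500 meal events, HbA1c spread ≈ 5.0–7.4 across at-risk/prediabetes/T2D)
without claiming a fit to any dataset. The generator does **not** emulate:
glucose–insulin physiology (no insulin dynamics, no meal-composition
effects beyond calories), overlapping-excursion interference beyond simple
superposition, sensor drift/compression artifacts, or annotator biases that
correlate across readers. A green test therefore establishes that the
algorithms implement their definitions and that the estimators recover
*planted* effects under the stated noise — not that the effect sizes
transfer to real cohorts.

`simulate_daily_outcome_cohort()` plants daily effects (defaults follow the
magnitudes a study of this design reports: category effects
−1.1/−4.0/−8.1 on TIR, +1.7/+5.8/+7.7 on mean glucose, +0.07/−0.3 per 1000
steps) with linear confounding of treatments by baseline glucose and
duration and a shared participant effect. The confounding default is
calibrated to the strongest level at which correct weighting restores the
|r| < 0.1 heuristic at ~400 participant-days — the regime the validation
scenario stipulates (balance fails before weighting, passes after); under
much stronger confounding that heuristic is unattainable at this sample
size for *any* correct weights, which is a property of the heuristic, not
of the estimator.

## 7. Numerical choices and degenerate inputs

* Timestamps are timezone-naive local clock time (the 04:00/23:59 rules are
  clock rules), ISO-8601 minute precision on disk; rows violating schema
  invariants are rejected with row-level diagnostics, never dropped
  silently.
* `mgr_3h` requires ≥ 2 samples and errors otherwise; a perfectly
  predicted treatment is caught by a density floor (1e-12) plus truncation;
  single-row treatment categories are flagged and survive via truncation;
  empty categories drop their contrast with a warning.
* Mixed-model failures fall back to fixed-effects propensity models with a
  logged warning rather than aborting; logistic separation in an outcome
  model is an error with a diagnostic.
* Determinism: all randomness flows from the caller's seed; identical seeds
  give byte-identical pipeline artifacts.
* Known start-time precision limit: the selected start time is the
  iAUC-best (earliest on ties) of the annotators' jittered timings, so its
  error inherits the jitter distribution; with 4 annotators at jitter
  SD 10 min, the earliest timing is within 15 min only ~76% of the time.
  Recovery contracts are therefore stated as medians at high jitter and as
  95%-within-one-sample at the default SD 5.

## 8. Known limitations

Meal detection requires annotations (automated CGM-only detection is out of
scope); the HbA1c map is a population model applied to individuals; the
wear detector is a simplified surrogate; weighted logistic outcome models
keep model-based z errors (the robust sandwich is implemented for linear
outcomes, where the weighted analyses live); and no unmeasured-confounding
sensitivity analysis is provided.
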