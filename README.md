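# cgmeal

Meal-event digital biomarkers and causal analysis for multimodal
digital-phenotyping studies that combine continuous glucose monitoring
(CGM), a hip-worn accelerometer, and smartphone food logging under
free-living conditions.

## What it does

Free-living food logs are noisy: items are entered in stages, logged late,
batch-logged at night, or forgotten. `cgmeal` turns three synchronized
streams — CGM glucose (15-min grid), per-minute step counts with wear
detection, and food logs corrected by multiple independent annotators —
into analysis-ready biomarkers, and estimates the causal effect of meal and
activity behaviour on glycemic control:

1. **Meal-event segmentation.** Food logs sharing a meal-occasion label
   within 60 min merge into a single meal timed at its first log. Annotated
   timings are clustered per participant-day with one-dimensional DBSCAN
   (`eps = 1.5` h, `min_samples = 2`); each group's start time is the member
   timing maximizing the 3-h incremental area under the CGM curve, and a
   group qualifies as a meal event when the maximum glucose rise over that
   segment is ≥ 18.6 mg/dL (between 04:00 and 23:59).
2. **Meal biomarkers.** For each event: the glucose response
   `MGR_3h = ∫₀^180 max(G(t) − G(0), 0) dt` (trapezoidal, min·mg/dL), the
   post-meal step count (1-h window), and the calorie content of the linked
   log. A cohort-level robust (Huber) regression
   `HbA1c = f(mean MGR_3h) + ε` maps each single meal's response to a
   *hypothetical HbA1c*; the meal is **elevated** when
   `f(MGR_3h) ≥ 5.7 %` (at-risk/prediabetes) or `≥ 6.5 %` (T2D).
3. **Daily biomarkers.** Per participant-day: an analysis window from the
   meal/wear rules, elevated meal count (categories 0/1/2/≥3), daily steps,
   baseline glucose, time in range `TIR_[54,140]` (sensitivity option:
   lower bound 70) and mean glucose, with the exclusion rules (no meals,
   < 10 h wear, first/last study day, sensor-limit samples ≤ 40 / ≥ 500
   mg/dL), plus per-modality adherence summaries.
4. **Causal analysis.** Generalized propensity scores with inverse
   probability weighting: Normal-density weights from a linear mixed
   propensity model for continuous treatments, normalized one-vs-rest
   logistic mixed models for the elevated-count categories; balance checks
   (weighted |r| < 0.1, pairwise SMD < 0.2); doubly robust weighted
   mixed-effects outcome regressions (random intercept per participant)
   with cluster-robust standard errors for weighted fits.
5. **Synthetic cohorts.** `simulate_cohort()` generates the whole
   multimodal bundle with planted ground truth (meal times, per-meal MGR
   contributions, the MGR→HbA1c line, logging errors, emulated annotators),
   and `simulate_daily_outcome_cohort()` plants known causal effects with
   treatment–covariate confounding, so every estimator is validated against
   known truth.

## Worked example

```r
library(cgmeal)
res <- run_pipeline(run_config(
  sim = sim_config(n_participants = 12, n_days = 10),
  seed = 42, out_dir = "out"))

res$mapper
#> HbA1c mapper (degree 1): HbA1c = 4.0736 + 0.00047918 * mean MGR_3h
#>   sigma = 0.1542, Pearson r = 0.941, MAE = 0.164

# four analyses: res$effects${elevated_count, daily_steps, post_meal_steps, calories}
res$effects$elevated_count$effects[, c("outcome", "term", "estimate", "se", "p_value")]
#>                     outcome    term estimate    se  p_value
#> tir.1                   tir  0 vs 1    -2.22 0.965 4.23e-02
#> tir.2                   tir  0 vs 2    -6.44 0.995 4.61e-05
#> tir.3                   tir 0 vs 3+    -8.77 1.190 1.42e-05
#> mean_glucose.1 mean_glucose  0 vs 1     1.72 0.732 3.83e-02
#> mean_glucose.2 mean_glucose  0 vs 2     2.30 0.921 2.96e-02
#> mean_glucose.3 mean_glucose 0 vs 3+     5.91 1.004 1.06e-04
```

Reading: on this synthetic cohort (319 qualified meal events, 87 included
participant-days), going from zero to two elevated meals in a day lowers
daily time-in-range by 6.4 percentage points (p < 0.01 under the p < 0.01
significance convention), while zero→one is not significant — the pattern
the planted effects encode. The meal-level analysis on the same run
estimates that 1000 extra post-meal steps reduce `MGR_3h` by ≈ 657
min·mg/dL and cut the odds of an elevated meal (odds ratio 0.14); inverse
probability weighting is skipped there because |cor(post-meal steps,
calories)| = 0.03 < 0.1, and the model adjusts for calories directly.

Artifacts written to `out/`: `meal_events.csv`, `meal_biomarkers.csv`,
`mapper.json`, `day_records.csv`, `adherence.csv`, `effects.csv`,
`balance.csv`, `manifest.json` (seed, options, config hash).

A command-line entry point with `simulate` / `segment` / `biomarkers` /
`daily` / `causal` / `run` subcommands is installed at
`system.file("cli", "cgmeal", package = "cgmeal")`.

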