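---
title: "Estimating who benefits from RRT in S-AKI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating who benefits from RRT in S-AKI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Renal replacement therapy (RRT) in sepsis-associated acute kidney injury
(S-AKI) is a textbook case of treatment-effect heterogeneity: trials of RRT
timing repeatedly find no average mortality benefit, yet clinicians are
convinced some patients are saved by it.  In observational ICU data the
treated are systematically sicker — clinicians initiate RRT in severe
cases — so naive arm contrasts are confounded, and an average effect, even
if identified, would not say *which* patient benefits.  `rrtuplift`
estimates the individual treatment effect (ITE) on 28-day survival from a
flat one-row-per-ICU-stay cohort table, using propensity matching to remove
measured confounding and class-transformation uplift modeling to rank
patients by expected benefit.

## The class transformation and its assumptions

For treatment flag `T` (RRT) and 28-day death flag `D`, define

    Z = 1  if (T = 1 and D = 0) or (T = 0 and D = 1),   else Z = 0.

If `P(T = 1 | X) = 1/2` — enforced in practice by 1:1 matching — then

    P(Z = 1 | X) = 1/2 [ P(survive | T = 1, X) + P(die | T = 0, X) ]
                 = 1/2 [ 1 + tau(X) ],

so `uplift(X) = 2 P(Z = 1 | X) - 1` equals the ITE
`tau(X) = P(survive | T=1, X) - P(survive | T=0, X)`.  A single
probabilistic classifier for `Z` therefore estimates the ITE.  The identity
needs (i) equal-probability treatment given `X` (matching makes this
approximately true for *measured* confounders only), and (ii) a calibrated
classifier.  `fit_class_transformation()` warns whenever the training arms
are unequal, since the identity then fails by construction.

The default learner is a gradient-boosted tree ensemble
(`xgboost`, `max_depth = 3`, `eta = 0.1`, `nrounds = 200`,
`min_child_weight = 20`, single thread): the Z label is extremely noisy
(its Bayes error is close to 1/2), so the configuration is deliberately
shallow and strongly regularized, and trees support exact additive
(tree-SHAP) attributions through `feature_contributions()`.  A
ridge-penalized logistic alternative (`learner = "glmnet"`) is provided for
users who prefer a linear, fully convex fit.  Missing covariates are
median-imputed with medians from the development cohort only.  Predicted
probabilities are clipped to `[1e-6, 1 - 1e-6]` before the `2P - 1`
transform so an overfit tree cannot emit a spurious uplift of exactly ±1.

## Evaluation: adjusted qini and AUUC

Rank each arm separately by the candidate score, descending.  For a
fraction `phi` in (0, 1], take the top `ceiling(phi * N_t)` treated and
`ceiling(phi * N_c)` controls and count observed 28-day survivors,
`n_t1(phi)` and `n_c1(phi)`.  The adjusted qini index is

    Q(phi) = n_t1(phi) / N_t - n_c1(phi) n_t(phi) / (N_t n_c(phi)),

which rescales the control survivor count by the selected treated/control
ratio so unequal arms remain comparable; at `phi = 1` it reduces exactly to
the overall survival-rate difference.  "Survivors" means *observed*
survival among the selected fraction: a qini computed on model-predicted
survival would evaluate the model against itself.  The AUUC is the
trapezoidal area between the curve and the random line, taken as the chord
from `(0, 0)` to `(1, Q(1))`; an uninformative ranker has expected AUUC 0.
The default grid is deciles; the curve depends on scores only through
within-arm ranks, so any strictly monotone rescaling leaves it unchanged
(this invariance is tested).  Ties are broken by a stable sort then by id,
making every curve reproducible; comparator rankers (`SOFA`, KDIGO stage)
default to higher-score-ranks-first.

## Propensity matching

`fit_propensity()` is a main-effects binomial GLM.  Right-skewed positive
labs (creatinine, lactate, WBC, urine output, fluid input, BUN) should be
entered on the log scale via `log_transform=`: severity plausibly acts
multiplicatively on these, and a linear-in-raw-scale propensity model is
misspecified for them, which shows up directly as residual post-match
imbalance.  `greedy_match()` processes treated subjects in descending
propensity order (hardest to match first — the common heuristic), matches
each to the nearest unmatched control by |logit(ps) difference| without
replacement, and skips a treated subject when the nearest control exceeds
the caliper.  The default caliper is 0.2 SD of the logit propensity, the
standard convention; matching on the logit scale behaves better in the
tails than matching on the probability.  Processing order and all ties are
broken by lowest id so results are exactly reproducible.  Balance is
reported as the absolute standardized mean difference with the pooled-SD
denominator (`sqrt((s_t^2 + s_c^2)/2)`; binary variables use
`sqrt((p_t(1-p_t) + p_c(1-p_c))/2)`), with |SMD| < 0.1 as the conventional
balance threshold.  When the pooled variance is zero the SMD is defined as
0 for equal means and is an error otherwise.

## Cohort construction

`kdigo_stage()` encodes the KDIGO staging rules as a declarative threshold
table (`kdigo_thresholds()`), creatinine criteria and urine-output criteria
staged independently and combined by maximum; RRT initiation forces stage
3.  Stage 1 is SCr 1.5–1.9× baseline or a ≥ 0.3 mg/dl rise within 48 h or
urine output < 0.5 ml/kg/h over 6–12 h; stage 2 is 2.0–2.9× or < 0.5
ml/kg/h for ≥ 12 h; stage 3 is ≥ 3.0×, SCr ≥ 4.0 mg/dl, RRT, < 0.3 ml/kg/h
for ≥ 24 h, or anuria ≥ 12 h.  The baseline-creatinine definition is the
caller's responsibility.  `apply_cohort_filters()` applies the study rules
— sepsis, highest KDIGO stage ≥ 1, first ICU admission, age ≥ 18, no ESRD,
potassium ≤ 6.5 mmol/l (strictly above 6.5 is an urgent dialysis indication
and is excluded) — and logs per-filter attrition.  The table carries both a
baseline and a highest KDIGO stage: inclusion filters on the *highest*
stage, so baseline stage 0 can legitimately appear in the analysis cohort;
conflating the two columns is a common source of apparent contradictions in
published S-AKI baseline tables.  Filters are conjunctive, so the retained
set is order-independent (tested); only the per-filter counts depend on
order.  One unit system is fixed per variable: creatinine in mg/dl
(÷ 88.4 from µmol/l) and glucose in mg/dl (× 18.016 from mmol/l).

## The synthetic cohort generator

The generator is the pipeline's ground-truth oracle, not a fixture: it
draws cohorts whose statistical structure matches what the analysis
assumes, with the true ITE stored per record.

* **Covariates** (`default_covariate_spec()`): log-normal for skewed labs
  and volumes, normal for vitals, integer-categorical for ordinal scores,
  with location/scale set to values typical of an adult ICU S-AKI
  population (e.g. age 67.5 ± 15.6 y, SOFA ≈ 5.5 ± 3, lactate mean 3.31
  SD 2.61 mmol/l, creatinine mean 1.39 SD 0.99 mg/dl, urine output
  median ≈ 1.8 l/24h).  Log-normal parameters are derived from the
  arithmetic mean/SD via `lognormal_params()`.
* **Confounded treatment**: `logit P(T=1|X) = alpha + c * s(X)` where
  `s(X)` is a standardized severity index (mean of z-scores of SOFA,
  creatinine, lactate and negated urine output) and `c` is
  `confounding_strength` (default 1.0 log-odds per severity SD — strong,
  deliberately so, to mimic the clinical reality that sicker patients get
  RRT).  `alpha` is calibrated by bisection so the expected treated
  fraction hits `treat_fraction_target` (default 0.08, a realistic RRT
  rate in S-AKI; bisection to 1e-10 on [-30, 30]).
* **Outcome and effect**: control-arm death probability is logistic in
  severity (default baseline 30% at mean severity, 0.9 log-odds per SD);
  the ITE enters on the probability scale,
  `tau(X) = 0.07 - 0.08 z(urine output) + 0.06 z(lactate) + 0.05 z(WBC)`
  by default — an average absolute risk reduction of 7 points with SD
  ≈ 0.11, so benefit concentrates in oliguric, hyperlactatemic,
  high-WBC patients while a tail of patients is actively harmed.  The
  treated-arm probability is clipped to [0, 1]; the clip count is stored
  on the table (`attr(, "n_clipped")`) rather than silently discarded.
  Degenerate configurations (all probabilities 0 or 1) raise errors naming
  the offending parameter.
* **Determinism**: one master seed; each stage (covariates, treatment,
  outcome, inclusion flags) uses a deterministically derived sub-seed, so
  a fixed seed reproduces the table bit-for-bit.

What the generator does *not* emulate: longitudinal/hourly trajectories,
informative censoring or competing risks (the 28-day outcome is fully
observed), measurement error, missingness, unmeasured confounding, or
correlation between covariates beyond what the severity index induces.
Tests passing on these cohorts therefore demonstrate correctness of the
estimators under the stated assumptions — not robustness to violations
real EHR data would add.

## Benefit profiling

`compare_groups()` makes the usual "as appropriate" test choice explicit
and logs it per variable: categorical variables (≤ 4 distinct values by
default) get the chi-square test with Yates correction on 2×2 tables;
continuous variables get Student's t-test when Shapiro–Wilk at
`alpha = 0.05` rejects normality in neither group, otherwise the
Mann–Whitney U test.  No multiple-testing correction is applied by default
(the profiling is descriptive); `stats::p.adjust` can be applied to the
returned p-values by callers who want it.  `fit_benefit_logistic()` is a
main-effects binomial GLM reported as odds ratios with Wald 95% CIs; the
default six-variable set (urine output, creatinine, lactate, WBC, glucose,
respiratory rate) is configurable.

`build_nomogram()` uses the standard regression-nomogram construction:
variable `i` with coefficient `beta_i` and axis range `[lo, hi]` gets
`points_i(x) = 100 beta_i (x - x_ref_i) / K` with `x_ref_i` the axis end
minimizing `beta_i x` (so points are non-negative and a protective variable
scores highest at its low end) and `K = max_j |beta_j| range_j` (the most
influential variable spans 0–100).  Total points map back to probability
*exactly* through `plogis(lp0 + K/100 * total)`; the round-trip error
against the underlying GLM is at floating-point level, and the packaged
invariant requires < 0.01 over sampled profiles to allow for breakpoint
interpolation in exported tables.

`power_two_proportions()` reports the standard normal-approximation
two-sided power (pooled SE under the null, unpooled under the
alternative), plus a t-test-on-binary variant for comparability with
sample-size calculations framed as t-tests.  At the matched design point
used throughout (458 per arm, mortality 0.393 vs 0.323, alpha 0.05) both
give ≈ 0.60.  Published power claims of > 99.9% at this exact design point
do not recompute under any standard two-proportion or t-test formula; the
package reports the computed value.

## Numerical choices and degenerate inputs

* Top-`phi` selection uses ceiling counts per arm; `qini_at()` guards the
  `n_c(phi) = 0` division explicitly.
* All rankings (matching order, qini, benefit split) break ties by id,
  never by memory order, so every result is reproducible and relabeling
  ids permutes outputs consistently (tested).
* The benefit split assigns the extra record of an odd cohort to the high
  group (`ceiling(n/2)`).
* Separation in the propensity or benefit GLMs is detected (deviance
  collapse or runaway coefficients after a glm fit warning) and raised as
  an error rather than returned as a silently unstable fit; constant
  covariates are dropped from the propensity model with a warning.
* SMD with zero pooled variance: 0 when means agree, error otherwise.

## Problem sizes

The test suite exercises the Monte-Carlo properties at sizes chosen to
keep sampling error well below the asserted margins while running in
seconds: treated-fraction calibration at n = 100,000 (3 binomial SEs),
propensity-coefficient recovery at n = 50,000 (3 Wald SEs), null
calibration of P(Z=1|X) at n = 20,000, effect-recovery and balance
invariants over 5 seeds at n = 8,000 and 6,000, and 1,000-instance
brute-force equivalence for the qini computation at N ≤ 30.  The
acceptance script runs the full pipeline at n = 12,000 (≈ 750 matched
pairs), roughly the scale of a single-center observational S-AKI cohort.

## Limitations

Matching removes only measured confounding; the uplift identity is exact
only at `P(T|X) = 1/2`; the qini evaluation needs both arms represented
across the score range; and the generator's linear-in-z effect surface is
an easy case for a boosted-tree learner — real effect surfaces may be
harsher.  The pipeline performs a single fit with fixed hyperparameters
and no tuning loop; model selection on the development cohort would
require a nested split the package deliberately does not automate.
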