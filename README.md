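# lppselect

Variable selection with **low-prevalence binary predictors** (LPPs):
predictors present in fewer than 10% of subjects, as are common in clinical
screening tools and EHR-derived data. The package implements a head-to-head
comparison of two selection strategies on binary-predictor cohorts —
random-forest permutation-importance selection and AIC stepwise logistic
regression — together with the ROC machinery needed to compare them fairly
and a simulation harness that asks how predictor prevalence itself drives
the results. The motivating application is a paediatric sepsis screening
tool with 32 binary criteria, 18 of them LPPs.

## What it computes

**Data model.** Cohorts of `n` subjects with independent Bernoulli
predictors `x_j ~ Bern(p_j)` and a logistic outcome

    P(y = 1 | x) = logit⁻¹(β₀ + Σⱼ βⱼ xⱼ)

The default 32-predictor specification uses published screening-tool odds
ratios as the true `exp(βⱼ)` and calibrates `β₀` by Monte-Carlo root search
so the marginal outcome prevalence hits a target (15.1% by default).

**Forest arm.** Average the *unscaled* out-of-bag permutation importance
over repeated forests (reference: 25 × 10,000 trees), drop non-positive
importance predictors, then grow nested models over the ranked survivors
(`k = 3, 4, …`). Each nested model is scored by pooled out-of-fold
cross-validated class-vote probabilities and compared with the
all-predictor model by **DeLong's test for two correlated ROC curves** on
shared folds; the selected model is the smallest `k` with `p ≥ α`. The
sweep runs at `mtry ∈ {3, 6, 16}`.

**Regression arm.** Forward and backward stepwise logistic regression with
AIC as the sole criterion (no p-value stopping), Wald odds ratios with 95%
CIs, separation flagging for unstable rare-predictor estimates, and 10-fold
cross-validated AUC of the retained set.

**ROC statistics.** Mann–Whitney AUC (ties half-credited), DeLong
placement-value variance estimates, and stratified-bootstrap percentile
CIs (class counts preserved in every replicate).

**Simulation study.** Regenerate cohorts with every predictor's prevalence
floored at 10%, 20% and 30% (betas fixed, intercept recalibrated), run one
forest + one stepwise fit per dataset, and aggregate importance-rank
distributions, retention counts and AUC mean/SD per threshold.

## Worked example

```r
library(lppselect)
library(dplyr)

specs  <- default_predictor_specs()
cohort <- generate_cohort(specs, n = 3473, seed = 2026)
mean(cohort$outcome)
#> [1] 0.147

bw <- backward_stepwise(cohort, seed = 11)
glance(bw)
#> # A tibble: 1 × 7
#>   direction n_retained n_steps   aic cv_auc cv_ci_low cv_ci_high
#>   <chr>          <int>   <int> <dbl>  <dbl>     <dbl>      <dbl>
#> 1 backward          23       9 2481.  0.761     0.737      0.782

tidy(bw) |> arrange(desc(odds_ratio)) |> head(5)
#> # A tibble: 5 × 8
#>   term    estimate std_error statistic  p_value odds_ratio conf_low conf_high
#>   <chr>      <dbl>     <dbl>     <dbl>    <dbl>      <dbl>    <dbl>     <dbl>
#> 1 Severe8     1.99     0.376      5.30 1.17e- 7       7.34     3.51     15.3
#> 2 Severe5     1.77     0.188      9.43 4.24e-21       5.88     4.07      8.51
#> 3 Factor1     1.51     0.122     12.3  5.86e-35       4.53     3.56      5.76
#> 4 Factor4     1.37     0.288      4.75 1.99e- 6       3.93     2.23      6.91
#> 5 Severe7     1.15     0.298      3.85 1.20e- 4       3.14     1.75      5.64

imp <- average_importance(cohort, mtry = 3, n_trees = 500, n_repeats = 5,
                          seed = 7)
head(imp, 5)
#> # A tibble: 5 × 4
#>   predictor mean_importance sd_importance  rank
#>   <chr>               <dbl>         <dbl> <int>
#> 1 Severe5           0.00530     0.000261      1
#> 2 Factor1           0.00515     0.000202      2
#> 3 Factor4           0.00199     0.0000601     3
#> 4 Severe3           0.00184     0.0000439     4
#> 5 Severe8           0.00119     0.0000240     5
```

Reading it: on one synthetic cohort of 3473 subjects the backward
elimination keeps 23 of 32 predictors with a cross-validated AUC of 0.76
(95% CI 0.74–0.78); the largest fitted odds ratios belong to hypothermia
(`Severe8`, true OR 6.89, fitted 7.34), lactate (`Severe5`, true 6.30,
fitted 5.88) and age < 3 months (`Factor1`, true 4.60, fitted 4.53) —
rare, strong predictors recovered near their generating values. The
forest's averaged permutation importance ranks the same strong predictors
at the top: lactate and young age first, with the 1%-prevalence
hypothermia still inside the top five despite its rarity.

For the full pipeline on one cohort use `run_full_comparison(cohort)`
(forest sweep + both stepwise directions + side-by-side report), and
`autoplot()` on importance tables, selection runs and simulation results.
For the prevalence simulation:

```r
cfg <- simulation_config("desk", master_seed = 1)   # 20 datasets/threshold
rf  <- run_rf_simulation(cfg)
rf$auc_summary          # mean/SD AUC per prevalence threshold
summarize_rank_shift(rf$rank_counts, "original", "30%")
```

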