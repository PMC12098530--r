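---
title: "Variable selection with low-prevalence binary predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable selection with low-prevalence binary predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lppselect)
```

## The problem

Clinical screening tools often consist of many binary criteria, and a large
share of them are *low-prevalence predictors* (LPPs): present in fewer than
10% of subjects, sometimes in only 1-2%. Such predictors sit awkwardly in
variable selection. In logistic regression they produce large, unstable
coefficient estimates with inflated standard errors, and greedy procedures
may drop a rare but clinically crucial criterion. In random forests, a rare
binary split is chosen seldom and carries few subjects, so its permutation
importance is noisy.

`lppselect` implements, as a reusable and tested pipeline, a head-to-head
comparison of the two selection strategies on exactly this kind of data:

1. **Forest arm** — repeated-forest permutation-importance ranking followed
   by sequential nested-model selection against the full model;
2. **Regression arm** — forward and backward stepwise logistic regression
   under AIC, with Wald odds ratios;
3. a **prevalence-threshold simulation study** that regenerates the cohort
   with every predictor's prevalence floored at 10%, 20% and 30% and asks
   how rankings, retention and discrimination respond.

Because the motivating cohort (an emergency-department paediatric sepsis
screen) is not publicly available, the package ships a synthetic-cohort
generator that emulates its published structure, and all empirical claims
in this vignette are about that synthetic data model.

## The generating model

A cohort is `n` iid subjects. Predictor `j` is Bernoulli with prevalence
`p_j`; predictors are drawn independently. The outcome follows a logistic
model

    P(y = 1 | x) = plogis(b0 + sum_j beta_j x_j)

The default specification (`default_predictor_specs()`) has 32 predictors
in four categories (nine sepsis indicators, six risk factors, eight severe
illness features, nine moderate illness features). The `beta_j` are the
natural logs of the published full-model odds ratios for the corresponding
screening tool, so the generator's "truth" is a realistic effect-size
profile: mostly weak effects (OR near 1), a handful of strong ones
(OR 4.6-6.9), and the strong ones concentrated among rare predictors.

Per-predictor prevalences are *declared surrogates*: the real per-item
table is not public. Where a value is documented (hypotension 1%,
capillary refill 4%) it is used; the rest were fixed once so that the
published composition holds — 18 predictors below 10% prevalence, 12 of
them at or below 5% — with LPP values spread over 0.01-0.09 and common
predictors over 0.12-0.60. They are data, not code: everything is
overridable and round-trips through YAML/JSON (`read_predictor_specs()`),
with odds ratios accepted on the natural scale.

**Intercept calibration.** The marginal outcome prevalence is a design
target (15.1% by default), so `b0` is not free: `calibrate_intercept()`
root-solves `E[plogis(b0 + X beta)] = target` over a seeded Monte-Carlo
sample of predictor draws (`n_mc = 2e5` by default; the root is found to
`1e-10`). With all betas zero this reduces to the closed form
`qlogis(target)`, which the tests check. Monte-Carlo error at the default
`n_mc` keeps realised mean prevalence within about 0.1 percentage points
of target.

**What the generator does not emulate.** Independence between predictors
is the declared default: the real screening criteria are surely correlated
(two of them are literally combinations of others), and no public
information pins the joint distribution down. Passing tests therefore
demonstrate behaviour under independent predictors with logistic outcomes
— they say nothing about collinearity-driven pathologies (the combined
parental/health-care-worker concern item is the canonical example), about
missingness, or about continuous criteria. This is the main known
limitation of every empirical statement the package can make.

## The forest arm

`average_importance()` trains `n_repeats` forests with distinct derived
seeds and averages each predictor's **unscaled** out-of-bag permutation
importance — the mean over trees of the drop in OOB accuracy when the
predictor is permuted among that tree's OOB subjects, as computed by
`randomForest::importance(type = 1, scale = FALSE)`. The scaled variant
(importance divided by its standard error) is deliberately avoided: it
distorts comparisons across predictors with different split frequencies,
which is exactly the LPP-vs-common contrast under study. The reference
configuration for a definitive run is 25 repeats of 10,000 trees; the
package defaults are scaled down (5 x 500) so that interactive use and the
test suite stay within minutes on one CPU. Averaging is worth it: the SD
of the repeat-mean shrinks roughly like `1/sqrt(n_repeats)`, which a test
verifies directionally.

Ranks order by descending mean importance, ties broken lexicographically
by predictor name so reruns are bit-identical. Predictors with
non-positive mean importance are removed (`filter_negative()`; exact zero
counts as non-positive), and `sequential_selection()` then grows nested
models over the ranked survivors from `k_min = 3` upward. Each nested
model is scored by pooled out-of-fold predictions from stratified K-fold
cross-validation (class-vote fraction as the score, no calibration), with
a stratified-bootstrap CI, and compared against the full reference model —
**all** candidate predictors, not just positive-importance ones — by
DeLong's paired test *on the same folds*. Sharing one fold assignment
across every nested model and the full model is what makes the DeLong
comparison paired and valid; the fold assignment is stratified by outcome
so every fold sees both classes.

The parsimonious-model rule picks the smallest `k` whose two-sided DeLong
p-value against the full model is at least `alpha` (default 0.05). When no
sub-model qualifies, `chosen_k` is `NA` — a real outcome (large `mtry`
runs reproduce it), not an error. Two degenerate thresholds are pinned by
tests: at `alpha = 0` every sub-model qualifies, so `chosen_k = k_min`; at
`alpha = 1` only an exact duplicate of the full model (p identically 1)
can qualify, which happens precisely when the ranked set equals the full
candidate set. A scoring subtlety worth knowing: with very few binary
predictors, hard majority votes saturate and tie heavily, so a small
sub-model can score *below* its information content; vote-fraction scores
become smoother as predictors are added. This is a property of
classification-vote forests generally, and one reason the sequential curve
climbs gradually rather than jumping.

`mtry_sweep()` repeats the whole procedure at `mtry = 3`, `6` (the
`sqrt(p)` default) and `16`, the canonical small/default/large contrast
for 32 predictors; values are configurable and no further hyperparameter
search is attempted (out of scope by design).

## The regression arm

`backward_stepwise()` starts from the full logistic model and greedily
removes the predictor whose removal lowers AIC most; `forward_stepwise()`
mirrors it from the intercept-only model. There is no p-value stopping
rule anywhere. AIC ties within `1e-8` prefer the smaller model, and tied
candidate moves break lexicographically, making trajectories
deterministic; the recorded trajectory (step, action, predictor, AIC) is
non-increasing in AIC, and backward runs are verified against an
exhaustive per-step single-removal enumeration and against
`MASS::stepAIC` as independent oracles.

The inner loop evaluates candidate models with `glm.fit` on a prebuilt
design matrix (a few hundred refits per run); the user-facing fits go
through `glm()` so standard errors and diagnostics are the familiar ones.
Separation — rare predictors perfectly aligned with the outcome — is
flagged when any |coefficient| exceeds 15 on the log-odds scale or IRLS
fails to converge. Flagged fits are reported as-is with their intervals
marked unreliable; no Firth-type penalisation is applied, because
unstable LPP estimates are part of the phenomenon being studied, not a
nuisance to correct away.

Selection runs once on the full data; the retained set is then
cross-validated as a *fixed* set (`cv_logistic_auc()` refits coefficients
per training fold but never re-runs selection). This mirrors the common
applied sequence and carries a known optimism — the CV AUC of a set chosen
on the same data is biased upward. Users wanting honest selection-adjusted
error need nested selection, which is out of scope here.

## ROC statistics

The AUC is the Mann-Whitney estimator (ties half-credited), computed via
midranks; tests pin its equality with exhaustive pair counting and with
the trapezoidal area under the empirical ROC curve to `1e-12`, and its
invariance under strictly increasing score transforms. DeLong's test for
two correlated ROC curves is built from placement values — for each
positive, the fraction of negatives it outscores, and symmetrically — with
the variance of the AUC difference assembled from their sample
(co)variances. The implementation agrees with `pROC::roc.test` to
`1e-10` and with a paired permutation oracle within 0.02, holds its
nominal 5% size under the null, and defines the degenerate zero-variance
comparison (identical scores) as `z = 0, p = 1`.

Confidence intervals use the stratified bootstrap: positives and
negatives are resampled separately with replacement, preserving class
counts (no replicate can lose a class), with the percentile interval at
`alpha = 0.05` and `n_boot = 2000` by default (tests use smaller
`n_boot`; the floor is 200). Percentile rather than BCa was chosen as the
simplest scheme consistent with stratified resampling; the method is
recorded in the returned estimate. Endpoints are clamped to bracket the
point AUC, so the reported triple is always internally consistent.

## The simulation study

`simulation_config()` fixes the design: four prevalence thresholds (the
original specs, then floors of 10%, 20%, 30% applied to the *generating*
prevalences via `apply_prevalence_floor()`), `n_datasets` cohorts per
threshold, one forest per dataset (not 25 repeats — ranking stability
across datasets replaces within-dataset averaging), `mtry = 3` by default
(the small value, which the sequential analysis stage favours), and
backward stepwise as the regression arm. Betas never change across
thresholds, so prevalence is the only moving part; by default the
intercept is recalibrated per threshold to hold outcome prevalence at
15.1%, because raising the prevalence of positive-beta predictors would
otherwise inflate the outcome rate and confound the AUC trend (a config
flag restores the fixed-intercept variant). The RF and SWR arms derive
identical per-dataset seeds, so they consume identical cohorts and arm
differences are method differences.

Aggregated outputs are: the empirical distribution of
importance ranks (1 = most important) per predictor per threshold, with
`summarize_rank_shift()` reducing pairs of thresholds to median-rank
shifts and IQR changes; stepwise retention counts per predictor per
threshold; and per-threshold mean/SD of the cross-validated AUC. The
headline qualitative behaviour — discrimination improves as predictor
prevalence rises, for both arms — is asserted by the test suite at desk
scale within two standard errors per adjacent threshold pair.

**Problem sizes.** Full scale is the definitive design: 1000 datasets per
threshold at n = 3473 with 10,000 trees and 10 folds — a cluster-sized
job. Desk scale, used by the test suite and suited to a laptop, is 20
datasets per threshold at n = 500 with 300 trees and 5 folds; the
`simulation_config()` validator caps desk runs at 50 datasets and 500
trees so the two regimes cannot be mixed accidentally. Per-dataset
checkpoint files (optional `checkpoint_dir`) make long runs resumable and,
because per-dataset tasks are independent, trivially parallelisable.

## Reproducibility choices

All randomness flows from one master seed through a counter-based LCG
derivation scheme (`derive_seed()`, scheme id `lcg-48271-v1`); any single
forest repeat, fold, bootstrap or simulated dataset is reproducible in
isolation, and no function touches the global RNG state (everything runs
under `withr::with_seed`). Degenerate cohorts (single-class outcome) are
regenerated with the next derived seed and counted. Stratified fold
assignments that still produce a single-class fold (possible only when a
class has fewer members than folds) are regenerated the same way. Run
manifests (`run_manifest()`) record command, config, seed, scheme and
versions; `export_comparison()` writes them beside the CSV tables.

## Known limitations

* Independent predictors: no correlation structure, hence no statement
  about redundant-criterion behaviour that motivates part of the original
  comparison.
* The CV-after-selection optimism discussed above.
* Class-imbalance resampling is deliberately not offered (it would inflate
  predictor prevalences, the very quantity under study), and `mtry` is not
  tuned beyond the three canonical values.
* Desk-scale simulation estimates are coarse (20 datasets); they support
  trend statements, not precise means.
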