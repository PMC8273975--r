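---
title: "Misclassified sampling strata in disproportionate stratified sampling: models, estimators, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Misclassified sampling strata: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misclassdss)
```

## The problem

Surveys that want reliable inference about rare subgroups oversample them:
with race/ethnicity proportions like 82% White, 10% Black, 1% Asian, 5%
Other, and 2% Hispanic, a simple random sample (SRS) of 2,500 contains
about 25 Asian and 50 Hispanic respondents — too few for stable logistic
regression coefficients. Disproportionate stratified sampling (DSS) fixes
per-stratum sample sizes (here 500 from each of the five strata) and
re-weights by the inverse selection probability `w_i = N*_h / n*_h`.

The complication this package studies: the sampling strata are built from
an error-prone administrative label `X*` (electronic-health-record
race/ethnicity), while the analysis uses the gold-standard self-reported
label `X` collected with the survey response. When `Pr(X* | X)` does not
depend on the outcome `Y` (non-differential misclassification), sampling
on `X*` is ignorable given `X`; when it does depend on `Y` (differential),
`X*` is a collider — a common descendant of `X` and `Y` — and any analysis
that conditions on the selection (by ignoring it, or by adjusting for `X*`)
is biased, while inverse-probability weighting remains valid.

## Generative model

Each replicate draws a finite cohort of `N = 100,000`:

* `X ~ categorical(0.82, 0.10, 0.01, 0.05, 0.02)` over (White, Black,
  Asian, Other, Hispanic), category 1 the reference;
* `low_income | X ~ Bernoulli(expit(-2.00 + 1.25·Black + 0.25·Asian +
  1.75·Other + 0.50·Hispanic))`;
* `Y | X, low_income ~ Bernoulli(expit(-0.75 - 0.25·Black - 0.50·Asian +
  1.25·Other - 1.50·Hispanic + 1.00·low_income))` — `Y` is trust in the
  healthcare system;
* `X* | X[, Y]` from a misclassification matrix (below).

All defaults live in `pop_config()`; they are the study conditions, not
tuning knobs.

## Misclassification matrices and the direction question

`ehr_misclass_matrices()` embeds the observed VUMC respondent
cross-tabulation of EHR-recorded versus self-reported race/ethnicity,
overall and stratified by the trust outcome. Its rows condition on the
*recorded* category — row percentages are `Pr(self-reported | EHR[, Y])` —
which is the `inverse` direction: simulation needs `Pr(X* | X[, Y])`.

Two readings are implemented (`as_generator()`, and the scenario option
`matrix_interpretation`):

* **`bayes_inverted`** (default): Bayes inversion of each row-conditional
  under a prior over recorded categories, uniform by default — numerically,
  column-normalize the row-percentage matrix and transpose. This is the
  default because it demonstrably reproduces the published operating
  characteristics of all three analysis strategies under both mechanisms,
  and because a uniform prior is the only choice that needs no external
  marginal. Inverting against an explicit marginal is available through
  `invert_direction()`; note that solving for a recorded-category marginal
  consistent with the *population* race proportions has no valid solution
  for the outcome-stratified tables (the linear solve turns negative), so
  a supplied-prior inversion is the principled route.
* **`direct`**: reuse the printed row percentages as `Pr(X* | X)` rows,
  re-reading the row index as the true category. Kept because it is the
  naive reading of a published matrix; under the differential mechanism it
  produces a very different (much larger) collider bias profile.

`degree_matrix(d, H, pattern)` builds the parametric family used for the
precision sweep: diagonal `1 - d`, off-diagonal mass `d` split uniformly
or proportionally to the empirical matrix's off-diagonal row profile. At
`d = 0` nobody is mislabeled; at `d = 0.5` half the cohort is.

## The three analysis strategies

All three regress `Y` on the true-category dummies plus `low_income`
(`fit_method()`):

* **design-agnostic** — plain unweighted maximum likelihood, ignoring the
  design;
* **model-based** — unweighted, adding the recorded-category dummies
  `X*` as covariates;
* **design-based** — maximizes the weighted pseudo-likelihood
  `sum_i w_i [y_i log p_i + (1 - y_i) log(1 - p_i)]` with
  `w_i = N*_h / n*_h`, variance by linearization:
  `A^{-1} B A^{-1}` with `A = X' W X` (`W = w p (1 - p)`) and
  `B = sum_i u_i u_i'`, `u_i = w_i (y_i - p_i) x_i`.

The fitter (`fit_logistic()`) is an IRLS implementation written to stop
exactly where the conventional GLM fitter stops: shrunken-mean starting
values, relative deviance-change tolerance `1e-8`, at most 25 iterations,
step-halving if an iterate would increase the deviance (the first Newton
step is taken unconditionally, since the starting values are fitted means
rather than a coefficient vector). Matching the conventional stopping rule
is substantive, not cosmetic: rare-group SRS replicates occasionally have
an all-zero outcome cell, the likelihood is then maximized at infinity,
and what such a replicate contributes to a Monte-Carlo summary is whatever
finite value the fitter reports (around −15 on the log-odds scale here).
Those fits satisfy the deviance criterion, are flagged `separated`
(|coefficient| > 15) for diagnostics, and are **retained** in summaries;
only fits that fail the deviance criterion within the iteration cap are
dropped (and counted). Dropping the separated fits instead would visibly
understate the SRS empirical SEs of the rare-group coefficients, which are
dominated by exactly these replicates.

Variance choices: Wald intervals with normal quantiles at all sample
sizes; the design-based sandwich defaults to the unstratified
with-replacement form (independent weighted units, no finite-population
correction), with a `variance = "stratified"` option that centers scores
within stratum and applies `n_h / (n_h - 1)`. The unstratified default
matches what a survey analysis gets when the design object carries only
weights; it is slightly conservative, and with five large strata the two
forms differ little.

`truncate_weights()` implements percentile-capping of weights (common in
applied survey work to limit the influence of extreme weights): values
above the chosen percentile — computed by linear interpolation between
order statistics, the host environment's default quantile definition,
fixed here because published analyses rarely state the rule — are set to
that percentile.

## Monte-Carlo harness

`scenario()` + `run_scenario()` orchestrate: generate population → apply
misclassification → draw designs (whole cohort, SRS `n = 2500`, DSS
500/stratum) → fit strategies → summarize mean estimate, empirical SE
(SD of estimates across replicates), and 95% Wald coverage against the
generating coefficients (the recorded-category dummies are scored against
zero, their value under any outcome model that excludes them). Replicate
`r` runs under its own seed drawn once from the scenario seed, so results
are independent of execution order and any single replicate can be
reproduced in isolation. Convergence failures are dropped per cell, not
per replicate, and counted.

`sweep_degree()` reruns a base scenario across degrees of non-differential
misclassification and reports, per method and parameter, the relative
uncertainty `SE_DSS / SE_SRS` (and its log2). Expected behavior: below
one for the rare-group coefficients at low degree (the point of DSS),
rising toward one as misclassification makes the DSS draw resemble an
SRS; the model-based curves spike at small positive degree where the
collinearity between `X` and `X*` is extreme.

## Replication sizes

The shipped full configuration (`inst/extdata/dss_study.yaml`) uses
10,000 replicates. The package's test and acceptance profile uses 2,000
replicates at the same population and sample sizes — chosen so a full
verification pass completes in minutes while keeping the Monte-Carlo
error of means near `se/sqrt(R)` ≈ 0.01 and of coverage near 0.5–1
percentage point. One caveat at any replication size: the SRS empirical
SEs of the Asian and Hispanic coefficients are dominated by the rare
all-zero-cell replicates (about 0.3% of draws), so those two numbers
carry far more Monte-Carlo variability than the usual `SD/sqrt(2(R-1))`
formula suggests — at 2,000 replicates, one extra or missing separated
replicate moves the Hispanic SRS SE by roughly ±0.07.

## What the generator does and does not emulate

It emulates: a finite cohort with realistic category imbalance, a
confounder-free outcome model whose coefficients are known exactly (so
bias and coverage are measurable), empirically calibrated differential
and non-differential label error, and exact design-weight bookkeeping.

It does not emulate: non-response (every sampled unit responds),
measurement error in `Y` or `low_income`, continuous covariates,
within-stratum clustering, or the many-way stratification of real
designs (a real antecedent study crossed six variables into hundreds of
strata; this package uses the five label categories directly). Passing
tests therefore validate the estimators and the harness under the stated
generative model, not robustness to those further complications.

## Known limitations

* The empirical matrices are respondent-level estimates carried over as
  truth; sampling error in the 604 underlying counts is not propagated.
* Only `H`-category single-variable strata; quotas exceeding a stratum
  take the whole stratum with weight 1 rather than reallocating.
* The weighted pseudo-likelihood treats weights as fixed known constants;
  calibration, raking, and propensity approaches are out of scope.
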