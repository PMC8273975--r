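# misclassdss

Simulation toolkit for a question that arises in survey-linked biobank
research: what happens to regression inference when the **sampling strata
of a disproportionate stratified sample (DSS) are built from a
misclassified variable** — for example, strata defined by
electronic-health-record (EHR) race/ethnicity that disagrees with the
self-reported race/ethnicity later collected by the survey and used in
the analysis?

The package generates finite populations from known logistic models,
applies empirically calibrated label error (non-differential or
differential with respect to the outcome), draws simple random samples
(SRS) and DSS samples with inverse-probability weights, fits three
analysis strategies, and summarizes their operating characteristics over
Monte-Carlo replicates. It is aimed at survey statisticians and
epidemiologists planning exposure-enriched designs with imperfect frames.

## The model and the three strategies

Each replicate draws a cohort of N = 100,000 with true race/ethnicity
X ∈ {White, Black, Asian, Other, Hispanic} at proportions
(0.82, 0.10, 0.01, 0.05, 0.02), a low-income indicator from

    logit Pr(L = 1 | X) = −2.00 + 1.25·I(Black) + 0.25·I(Asian) + 1.75·I(Other) + 0.50·I(Hispanic)

a trust outcome from

    logit Pr(Y = 1 | X, L) = −0.75 − 0.25·I(Black) − 0.50·I(Asian) + 1.25·I(Other) − 1.50·I(Hispanic) + 1.00·L

and a recorded label X\* from a misclassification matrix Pr(X\* | X[, Y]).
DSS samples 500 units from each X\* stratum; unit i in stratum h gets
weight w_i = N\*_h / n\*_h. The strategies, all regressing Y on the true
X dummies plus L:

* **design-agnostic** — ordinary unweighted maximum likelihood;
* **model-based** — unweighted, adding the X\* dummies as covariates;
* **design-based** — weighted pseudo-likelihood
  Σ_i w_i [y_i log p_i + (1−y_i) log(1−p_i)], variance by linearization
  (sandwich) A⁻¹BA⁻¹ with score contributions u_i = w_i (y_i − p_i) x_i.

When Pr(X\* | X) is free of Y, sampling on X\* is ignorable given X and
the unweighted strategies remain valid (and more precise). When the label
error depends on Y, X\* is a collider: conditioning on the selection
biases the unweighted strategies, and only the weighted one recovers the
generating coefficients. The Monte-Carlo harness measures exactly this,
plus the precision gain of DSS over SRS as a function of the degree of
misclassification.

## Worked example

```r
library(misclassdss)

# the embedded EHR-vs-self-report matrix (rows condition on the EHR label)
m <- ehr_misclass_matrices()
print(m$overall, digits = 3)
#>          White Black Asian Other Hispanic
#> White    0.944 0.007 0.000 0.042    0.007
#> Black    0.000 0.937 0.000 0.051    0.013
#> Asian    0.012 0.012 0.765 0.173    0.037
#> Other    0.480 0.041 0.130 0.276    0.073
#> Hispanic 0.240 0.162 0.017 0.050    0.531

# a 100-replicate run: SRS n = 2500 and DSS 500/stratum under
# non-differential misclassification
scn <- scenario(pop_config(), "ehr_nondifferential",
                designs = list(srs = 2500, dss = 500),
                reps = 100, seed = 42, name = "demo")
res <- run_scenario(scn)
render_summary_table(res$summary)
```

Each cell is `mean (empirical SE) coverage%` across replicates:

```
              dss/design_agnostic dss/design_based   dss/model_based    srs/design_agnostic
(Intercept)   "-0.74 (0.06)96.0"  "-0.74 (0.07)96.0" "-0.73 (0.10)94.0" "-0.75 (0.06)91.0"
Black         "-0.25 (0.10)98.0"  "-0.25 (0.11)96.0" "-0.27 (0.26)96.0" "-0.27 (0.16)93.0"
Asian         "-0.52 (0.20)96.0"  "-0.54 (0.26)95.0" "-0.51 (0.27)96.0" "-0.87 (1.56)95.0"
Other         "1.22 (0.14)95.0"   "1.21 (0.21)94.0"  "1.23 (0.20)91.0"  "1.26 (0.20)96.0"
Hispanic      "-1.62 (0.40)97.0"  "-1.66 (0.43)95.0" "-1.63 (0.42)94.0" "-1.58 (0.46)98.0"
low_income    "1.00 (0.10)97.0"   "1.00 (0.14)96.0"  "1.00 (0.10)97.0"  "1.01 (0.13)91.0"
```

Reading it: all strategies are nearly unbiased here (the mechanism is
non-differential), the rare-group coefficients (Asian, Hispanic) are far
more precise under DSS than under SRS (0.20 vs 1.56 for Asian — the SRS
column is destabilized by replicates with almost no Asian respondents),
and the design-based weights cost some precision relative to the
design-agnostic fit. Rerunning with `"ehr_differential"` shows the
unweighted columns acquiring large biases while the design-based column
stays on target.

Larger runs are driven by YAML configurations
(`inst/extdata/dss_study.yaml`, 10,000 replicates) through
`run_config()` / `run_sweep_config()` or the thin CLI:

```sh
Rscript inst/cli/misclassdss.R simulate --config inst/extdata/dss_study_test.yaml --out out/
Rscript inst/cli/misclassdss.R render --summary out/nondifferential_summary.csv
```

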