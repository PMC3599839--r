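# twopartmm

Longitudinal count outcomes in epidemiology — hypoglycaemic events,
hospitalisations, falls, sports injuries — often carry far more zeros than a
Poisson distribution with the same mean would produce. `twopartmm` fits and
compares the three mixed models commonly considered for such data:

* a **linear mixed model**,
  `y_ij = x_ij' β + z_ij' b_j + ε_ij`, treating the count as Gaussian;
* a **Poisson mixed model** with log link,
  `y_ij ~ Pois(exp(x_ij' β + z_ij' b_j))`;
* a **two-part joint mixed model** (binomial/Poisson): a mixture
  `Pr(y_ij) = π1 · g(y_ij; 0) + π2 · g(y_ij; μ_ij)` of a point mass at zero
  and a Poisson count part, where **one shared linear predictor**
  `η_ij = x_ij' β + z_ij' b_j` drives both the non-zero class probability
  (`π2 = logit⁻¹(η_ij)`, logit link) and the count mean (`μ_ij = exp(η_ij)`,
  log link). Each covariate therefore gets a single coefficient governing
  both whether events occur and how many — the preferred reading when the
  outcome is one process, not two.

Subject-specific random intercepts (optionally plus random slopes for time)
are mean-zero Gaussian and are integrated out of the likelihood by
**adaptive Gauss–Hermite quadrature**. The package also implements the
accompanying comparison protocol — BIC, mean squared residual (MSR) of
empirical-Bayes predictions, observed-vs-predicted scatter plots, and the
percentage of observed zeros predicted as zero — plus a McDonald–Moffitt
style decomposition of the shared coefficient's marginal effect, and a
seeded generator of realistic three-wave cohorts (monotone dropout,
~60% zeros) for simulation studies.

## Worked example

```r
library(twopartmm)

cohort <- simulate_cohort(cohort_config(n_subjects = 770, seed = 1))
summarize_events(cohort, group_by = "education")

fits <- list(
  linear  = twopartmm(cohort, family = "linear"),
  poisson = twopartmm(cohort, family = "poisson"),
  twopart = twopartmm(cohort, family = "twopart"))
compare_models(fits)
```

```
Model comparison (lower BIC / MSR is better)
   model      bic   msr zero_accuracy converged best_bic best_msr
  linear 8871.889 1.777        69.765      TRUE    FALSE    FALSE
 poisson 5623.077 1.567        77.527      TRUE    FALSE     TRUE
 twopart 5335.118 1.869        76.895      TRUE     TRUE    FALSE
```

The two-part joint model has by far the lowest BIC, and both count families
classify observed zeros (predicted value below 0.5) much better than the
linear mixed model. Coefficients of the count families are prevalence-rate
log-ratios:

```r
coef(summary(fits$twopart))        # Coef., Std. Err., z, P > |z|
rate_ratio(coef(fits$twopart)[["education_high"]])
#>        coef ratio pct_change
#> 1 0.6565445  1.93         93
```

so highly educated subjects have a 93% higher event rate in this simulated
cohort. The shared coefficient's marginal effect splits into its count and
participation parts with
`decompose_marginal_effect(fits$twopart, "education_high")`.

A thin command-line wrapper covers the same pipeline:

```sh
exec/twopartmm simulate --config cohort.cfg --outdir out
exec/twopartmm fit --input out/cohort.csv --family twopart --outdir out
exec/twopartmm compare --input out/cohort.csv --families linear,poisson,twopart --outdir out
```

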