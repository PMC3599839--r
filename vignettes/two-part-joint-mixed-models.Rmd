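---
title: "Two-part joint mixed models for longitudinal counts with excess zeros"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-part joint mixed models for longitudinal counts with excess zeros}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Count outcomes collected repeatedly on the same subjects — hypoglycaemic
events in diabetes patients over a treatment period, falls, injuries,
hospitalisations — are typically overdispersed, and the dominant source of
overdispersion is an excess of zeros: in a cohort of this kind well over
half the subject-wave records can be zero. Treating such an outcome as
Gaussian ignores its discreteness and its spike at zero; a Poisson mixed
model accommodates the discreteness and the within-subject correlation but
still ties the zero probability to the mean, `Pr(0) = exp(-mu)`.

`twopartmm` implements the third option alongside those two baselines: a
two-part joint mixed model in which the outcome follows a mixture of a
point mass at zero and a Poisson distribution,

$$\Pr(y_{ij} \mid x_{ij}) = \pi_1\, g(y_{ij}; 0) + \pi_2\, g(y_{ij};
\mu_{ij}), \qquad \pi_2 = 1 - \pi_1,$$

with $g$ the Poisson pmf. The defining feature of the *joint* (shared
coefficient) form is that a single linear predictor
$\eta_{ij} = x_{ij}'\beta + z_{ij}' b_j$ drives both parts: the non-zero
class probability through a logit link, $\pi_2 = \operatorname{logit}^{-1}
(\eta_{ij})$, and the count mean through a log link, $\mu_{ij} =
e^{\eta_{ij}}$. Every covariate then has one coefficient, appropriate when
the outcome is a single process (how prone is this patient to events) rather
than two separable ones (whether vs how much, as in smoking analyses, for
which the `sharing = "separate"` variant with its own zero-part
coefficients is provided).

The random effects $b_j$ — a subject intercept, optionally plus a linear
slope on the 0-based wave index — are mean-zero Gaussian with free SDs and
intercept–slope correlation, shared between both parts of the mixture.

### Design decisions around the sharing structure

The shared form as implemented uses one predictor — intercept, covariate
effects and random effects all common to the two links. This is the only
reading that yields a single coefficient per covariate in the reported
tables, and it is the package default. The `separate` mode frees the
fixed effects of the zero part while keeping the random effects shared; a
fully bivariate random-effect structure with a free cross-part correlation
is out of scope.

Both zero-part forms are available. As written above the mixture is a
*zero-inflation*: the Poisson component also produces zeros, so
$\Pr(y=0) = \pi_1 + \pi_2 e^{-\mu}$. The *hurdle* reading — all zeros from
the zero class, the count part zero-truncated — is selected by
`zero_part = "hurdle"`. Inflation is the default because it is what the
mixture formula literally says; on zero-heavy data the two fit similarly
but their coefficients are not interchangeable.

## Estimation

The marginal likelihood integrates each subject's conditional likelihood
over the random effects. For the linear family this is a closed-form
multivariate Gaussian, evaluated per wave-pattern via Cholesky
factorization. For the count families the package uses adaptive
Gauss–Hermite quadrature (AGQ):

1. work in the standardized scale $b = L u$, $u \sim N(0, I)$, with $L$ the
   Cholesky factor of the random-effect covariance;
2. find each subject's posterior mode $\hat u_j$ of
   $q(u) = \log p(y_j \mid u) - \tfrac12 \|u\|^2$ by a damped, vectorized
   Newton search (numeric derivatives, step capped at 3, curvature clamped
   negative), warm-started from the previous optimizer iteration;
3. re-center the Gauss–Hermite grid at $\hat u_j$ and re-scale it by the
   local curvature (per-subject Cholesky of the negated Hessian inverse;
   tensor product across the two dimensions when a random slope is
   present), and accumulate the quadrature sum on the log scale.

With one node this reduces to the Laplace approximation; the default is 15
nodes per dimension. On cohorts of the size simulated below the maximized
log-likelihood moves by well under $10^{-3}$ between 15 and 25 nodes, and
the replicate studies in the tests use 9 nodes, which agrees with 15 to
about $10^{-5}$ on the coefficient scale while being noticeably faster. If
the mode search fails the rule falls back to the non-adaptive grid with a
warning.

Free parameters are optimized by BFGS on an unconstrained scale (log SDs,
atanh correlation). Starting values are the fixed-effects fit (least
squares or IRLS Poisson) with all SDs at 0.5. Convergence is declared on
relative log-likelihood change below `tol` (default 1e-8). The linear
predictor is clamped to $\pm 30$ inside the count-family densities so that
extreme trial steps remain finite; at the optimum this bound is never
active for realistic data.

Standard errors are the square roots of the inverse observed information,
computed by central finite differences of the log-likelihood at the
optimum and mapped to the natural scale by the delta method; `z` and the
two-sided Gaussian `P > |z|` follow. Random-effect SDs estimated below
`boundary_tol` (1e-6) are flagged as boundary and their SEs suppressed, as
is the degenerate all-zero-outcome case where the zero class absorbs all
mass. Empirical-Bayes random effects are posterior means computed with the
same adaptive rule (closed-form shrinkage for the linear family), and
subject-level predictions evaluate the family mean at
$\hat\eta = x'\hat\beta + z'\hat b_j$: $\hat\eta$, $e^{\hat\eta}$,
$\hat\pi_2 e^{\hat\eta}$, or $\hat\pi_2\hat\mu/(1 - e^{-\hat\mu})$ for the
hurdle.

`random = "none"` fits the fixed-effects counterpart of each family (every
random-effect SD held at zero), which is both useful as a baseline and the
cleanest way to exercise the variance-collapse limit against `glm`/`lm`.

## The comparison protocol

`compare_models()` assembles, per fitted model:

* **BIC** $= -2\ell + k \ln n$, with $n$ the number of subject-wave
  records by default (`bic_n = "subjects"` switches to clusters; the
  software convention behind published tables is not always stated, so
  both are exposed);
* **MSR**, the mean squared observed-minus-predicted residual of the
  empirical-Bayes predictions (marginal predictions via
  `include_ranef = FALSE`);
* **zero accuracy**: the percentage of observed zeros whose predicted
  expected value falls below 0.5 — nearest-integer rounding to zero. The
  threshold is exposed because "correctly estimated zeros" admits several
  formalizations; this one is the package's definition.

`rate_ratio()` exponentiates a log-link coefficient into a prevalence rate
ratio with its percent-change reading, and
`decompose_marginal_effect()` splits the marginal effect of a shared
coefficient at a chosen $\eta$ (default: the mean fitted predictor) into

$$\frac{\partial E[y]}{\partial x_k} = \underbrace{\pi_2 \mu
\beta_k}_{\text{count}} + \underbrace{\mu\, \pi_2 (1 - \pi_2)
\beta_k}_{\text{participation}},$$

the change in intensity among those above the limit weighted by the
probability of being above it, plus the change in that probability weighted
by the expected count. The identity with the numeric derivative of
$E[y] = \pi_2(\eta)\,e^\eta$ is verified to $10^{-6}$ in the tests. The
decomposition is defined for the shared inflation model only.

## The cohort simulator

`cohort_config()` / `simulate_cohort()` generate cohorts from the exact
data-generating processes the models assume, so every estimator can be
tested end to end without any external data. The default configuration
emulates the margins of a three-wave diabetes cohort:

* 770 subjects at baseline, waves at 0/3/6 months, monotone dropout with
  cumulative retention (1, 0.80, 0.66) — denominators back-calculated from
  the published per-wave event counts and percentages;
* a binary education covariate with prevalence 0.47 (low = reference);
* the shared two-part process with education effect 0.6 and
  random-intercept SD 1.0; intercept −0.203 and wave effects 0.162 / 0.197
  solved numerically (quadrature + root-finding) so the population zero
  fraction declines 61.4% → 57.3% → 56.4% across waves, matching the
  observed complement of the with-event percentages.

These are emulation targets for the *structure* of such data, chosen once;
they are not a reconstruction of the underlying study, whose raw data are
not available. Features of real cohorts the generator deliberately omits:
dropout is independent of the outcome (MCAR; an outcome-dependent mechanism
would need its own model and the source says nothing about the real
missingness), covariates are time-constant, and the count part is Poisson,
so the simulated median among subjects with events is lower than the
published medians (which suggest extra overdispersion beyond the zero
excess). Passing tests on these cohorts therefore demonstrate correctness
of the estimators under their own assumptions, not robustness to
misspecification.

`theoretical_moments()` integrates the zero probability and mean of the
configured process over the random effects with a 60-node rule and serves
as the simulator's analytic oracle in the tests.

## Numerical choices and degenerate inputs

* $\mu = 0$ is an exact point mass at zero (`poisson_logpmf(0, 0) = 0`),
  needed by the first mixture component, not an error.
* Mixture and truncated densities are evaluated on the log scale
  (log-sum-exp; `log(-expm1(-mu))`) so extreme predictors do not overflow.
* The wave time score for random slopes is the 0-based wave index, not
  months: the categorical fixed part fixes no time metric, and the index
  keeps the slope variance on an interpretable per-wave scale.
* Available-case analysis: records with missing outcomes are dropped (and
  counted) by the reader; the likelihood runs over observed records only,
  which is valid under MCAR/MAR-given-covariates like any mixed model.
* An all-zero outcome under the two-part family is fitted but flagged
  boundary/non-converged, with SEs suppressed, since the zero class
  absorbs all mass.
* Replicate studies in the acceptance material use 20 cohorts of 750
  subjects (recovery/coverage) and 50 cohorts of 770 subjects (model
  ordering); the in-package test suite runs the ordering study at 25
  replicates, sizes chosen to keep the default suite quick while leaving
  the binomial noise on an 80% threshold comfortably small.

## Known limitations

* No negative-binomial or ZINB count part; overdispersion beyond the zero
  excess is not modelled.
* No sandwich/robust standard errors and no likelihood-ratio tests;
  inference is Wald.
* The `separate` mode shares the random effects between parts; a free
  cross-part random-effect correlation is not implemented.
* BIC values are comparable across the two count families (same discrete
  support) but comparisons against the linear family's continuous density
  inherit the usual caveat of mixing density types; the protocol reports
  them side by side regardless, as the comparison it mirrors does.
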