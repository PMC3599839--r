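Package: twopartmm
Title: Two-Part Joint Mixed Models for Longitudinal Counts with Excess Zeros
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits three longitudinal models for non-negative count outcomes
    with an excess of zeros: the linear mixed model, the Poisson mixed model,
    and a two-part joint binomial/Poisson mixed model in which a single set
    of regression coefficients drives both the zero-membership (logit link)
    and the count mean (log link). Random intercepts and random slopes for
    time are integrated out of the likelihood by adaptive Gauss-Hermite
    quadrature. Includes empirical-Bayes prediction, model comparison by BIC,
    mean squared residual and zero-classification accuracy, a marginal-effect
    decomposition for the shared coefficient, and a seeded generator of
    realistic longitudinal cohorts with monotone dropout for simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    statmod
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mvtnorm,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
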