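# Shared fixtures and independent oracles for the test suite.

# Two subjects fully observed at three waves.
toy_longdata <- function() {
  d <- data.frame(
    id = rep(c("a", "b"), each = 3),
    t = rep(c("T0", "T1", "T2"), 2),
    education = rep(c("low", "high"), each = 3),
    y = c(0L, 1L, 4L, 0L, 0L, 2L))
  d$education <- factor(d$education, levels = c("low", "high"))
  longitudinal_data(d, subject = "id", wave = "t", outcome = "y",
                    covariates = "education")
}

small_cohort <- function(n = 80, seed = 42, ...) {
  simulate_cohort(cohort_config(n_subjects = n, seed = seed, ...))
}

# Brute-force dense-grid marginal log-likelihood for random-intercept
# models: trapezoid rule over b in [-8 sd, 8 sd]. Independent of the
# adaptive quadrature path it cross-checks.
grid_marginal_loglik <- function(dd, pl, spec, npts = 10001) {
  sd_b <- pl$sd_intercept
  bs <- seq(-8 * sd_b, 8 * sd_b, length.out = npts)
  h <- bs[2] - bs[1]
  M <- vapply(bs, function(b)
    subject_conditional_loglik(dd, pl, matrix(b, dd$n_subjects, 1L), spec) +
      stats::dnorm(b, 0, sd_b, log = TRUE),
    numeric(dd$n_subjects))
  M <- matrix(M, nrow = dd$n_subjects)
  mx <- apply(M, 1L, max)
  sum(mx + log(rowSums(exp(M - mx)) * h))
}
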