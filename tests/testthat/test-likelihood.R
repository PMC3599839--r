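spec1 <- list(family = "poisson", random = "intercept", n_quad = 15)
spec_tp <- list(family = "twopart", zero_part = "inflation",
                sharing = "shared", random = "intercept", n_quad = 15)

test_that("unconstrained transform round-trips exactly", {
  spec <- list(family = "linear", random = "intercept_slope")
  pl <- list(beta = c("(Intercept)" = 0.3, x = -1.2), beta_zero = NULL,
             sd_intercept = 0.8, sd_slope = 0.25, rho = -0.4,
             sd_resid = 1.7)
  th <- twopartmm:::par_pack(pl, spec)
  back <- twopartmm:::par_unpack(th, spec, names(pl$beta))
  for (nm in c("sd_intercept", "sd_slope", "rho", "sd_resid"))
    expect_equal(back[[nm]], pl[[nm]], tolerance = 1e-12)
  expect_equal(back$beta, pl$beta, tolerance = 1e-12)
})

test_that("subject conditional log-likelihood is additive and composes", {
  d <- data.frame(id = c("a", "a", "b"), t = c("T0", "T1", "T0"),
                  y = c(2L, 2L, 1L))
  ld <- longitudinal_data(d, "id", "t", "y")
  dd <- build_design(ld, waves = FALSE)
  pl <- list(beta = c("(Intercept)" = 0.4))
  ll <- subject_conditional_loglik(dd, pl, matrix(0, 2, 1), spec1)
  # b = 0, poisson: each record contributes dpois(y, exp(x beta))
  expect_equal(ll[1], 2 * dpois(2, exp(0.4), log = TRUE))
  expect_equal(ll[2], dpois(1, exp(0.4), log = TRUE))
  # with a random effect the predictor shifts by b
  ll_b <- subject_conditional_loglik(dd, pl, matrix(c(0.5, -1), 2, 1), spec1)
  expect_equal(ll_b[2], dpois(1, exp(0.4 - 1), log = TRUE))
  expect_error(subject_conditional_loglik(dd, pl, matrix(0, 2, 2), spec1),
               "dimension mismatch")
})

test_that("three-record subject sums three hand-evaluated terms", {
  d <- data.frame(id = "a", t = c("T0", "T1", "T2"), y = c(0L, 3L, 1L))
  ld <- longitudinal_data(d, "id", "t", "y")
  # second subject so the fit/design machinery has >= 2, not needed here
  dd <- build_design(ld, waves = TRUE)
  beta <- c("(Intercept)" = 0.2, waveT1 = 0.5, waveT2 = -0.3)
  b <- 0.7
  etas <- c(0.2, 0.7, -0.1) + b
  expect_equal(
    subject_conditional_loglik(dd, list(beta = beta), matrix(b, 1, 1),
                               spec_tp)[1],
    sum(twopart_logpmf(c(0L, 3L, 1L), etas)))
})

test_that("linear marginal likelihood matches the bivariate closed form", {
  skip_if_not_installed("mvtnorm")
  d <- data.frame(id = c("a", "a"), t = c("T0", "T1"), y = c(1L, 3L))
  ld <- longitudinal_data(d, "id", "t", "y")
  dd <- build_design(ld, waves = FALSE)
  pl <- list(beta = c("(Intercept)" = 1.5), sd_intercept = 0.9,
             sd_resid = 1.2)
  spec <- list(family = "linear", random = "intercept")
  V <- matrix(0.9^2, 2, 2) + diag(1.2^2, 2)
  expect_equal(twopartmm:::linear_marginal_loglik(dd, pl, spec),
               mvtnorm::dmvnorm(c(1, 3), rep(1.5, 2), V, log = TRUE))
  # variance-collapse limit: independent Gaussian densities
  pl0 <- list(beta = pl$beta, sd_intercept = 1e-12, sd_resid = 1.2)
  expect_equal(twopartmm:::linear_marginal_loglik(dd, pl0, spec),
               sum(dnorm(c(1, 3), 1.5, 1.2, log = TRUE)), tolerance = 1e-9)
})

test_that("adaptive quadrature reproduces the closed-form linear marginal", {
  coh <- small_cohort(n = 25, seed = 3, family = "linear",
                      beta = c("(Intercept)" = 1, education_high = 0.5),
                      sd_resid = 1.1)
  dd <- build_design(coh, covariates = "education", waves = TRUE)
  pl <- list(beta = c("(Intercept)" = 0.8, education_high = 0.4,
                      waveT1 = 0.1, waveT2 = 0.2),
             sd_intercept = 0.7, sd_resid = 1.1)
  spec_lin <- list(family = "linear", random = "intercept", n_quad = 15)
  expect_equal(agq_marginal_loglik(dd, pl, spec_lin, n_quad = 15),
               twopartmm:::linear_marginal_loglik(dd, pl, spec_lin),
               tolerance = 1e-6)
})

test_that("quadrature rule integrates the Gaussian density to one", {
  for (nq in c(1, 2, 5, 15, 25)) {
    r <- twopartmm:::gh_rule(nq)
    expect_equal(sum(r$weights) / sqrt(pi), 1, tolerance = 1e-10)
  }
  # a subject whose conditional likelihood is ~ 1 contributes ~ log(1) = 0
  d <- data.frame(id = c("a", "b"), t = "T0", y = c(0L, 0L))
  ld <- longitudinal_data(d, "id", "t", "y")
  dd <- build_design(ld, waves = FALSE)
  pl <- list(beta = c("(Intercept)" = -30), sd_intercept = 0.5)
  expect_equal(agq_marginal_loglik(dd, pl, spec1, n_quad = 7), 0,
               tolerance = 1e-8)
})

test_that("AGQ agrees with a dense-grid integral on small instances", {
  for (fam in c("poisson", "twopart")) {
    coh <- small_cohort(n = 5, seed = 11, family = fam,
                        beta = c("(Intercept)" = 0.1, education_high = 0.6,
                                 waveT1 = 0.15, waveT2 = 0.2))
    dd <- build_design(coh, covariates = "education", waves = TRUE)
    pl <- list(beta = c("(Intercept)" = -0.1, education_high = 0.5,
                        waveT1 = 0.1, waveT2 = 0.15), sd_intercept = 0.9)
    spec <- if (fam == "poisson") spec1 else spec_tp
    expect_equal(agq_marginal_loglik(dd, pl, spec, n_quad = 15),
                 grid_marginal_loglik(dd, pl, spec), tolerance = 1e-4)
  }
})

test_that("two-dimensional AGQ matches a tensor dense grid", {
  d <- data.frame(id = rep(c("a", "b"), each = 3),
                  t = rep(c("T0", "T1", "T2"), 2), y = c(0L, 2L, 5L, 1L, 0L, 0L))
  ld <- longitudinal_data(d, "id", "t", "y")
  dd <- build_design(ld, waves = FALSE, random = "intercept_slope")
  pl <- list(beta = c("(Intercept)" = 0.3), sd_intercept = 0.8,
             sd_slope = 0.5, rho = 0.3)
  spec <- list(family = "twopart", zero_part = "inflation",
               sharing = "shared", random = "intercept_slope")
  # dense tensor grid over (b1, b2)
  Sig <- twopartmm:::ranef_cov(pl, spec)
  g <- seq(-6, 6, length.out = 301)
  b1 <- 0.8 * g; b2 <- 0.5 * g
  h1 <- b1[2] - b1[1]; h2 <- b2[2] - b2[1]
  ll_grid <- numeric(2)
  Sinv <- solve(Sig)
  for (s in 1:2) {
    acc <- -Inf
    for (x1 in b1) {
      bmat <- cbind(rep(x1, length(b2)), b2)
      quad <- -0.5 * rowSums((bmat %*% Sinv) * bmat)
      lprior <- quad - log(2 * pi) - 0.5 * determinant(Sig)$modulus[1]
      cll <- vapply(seq_along(b2), function(i) {
        B <- matrix(0, 2, 2); B[s, ] <- bmat[i, ]
        subject_conditional_loglik(dd, pl, B, spec)[s]
      }, 0)
      m <- max(acc, max(cll + lprior))
      acc <- m + log(exp(acc - m) + sum(exp(cll + lprior - m)))
    }
    ll_grid[s] <- acc + log(h1 * h2)
  }
  expect_equal(agq_marginal_loglik(dd, pl, spec, n_quad = 21,
                                   per_subject = TRUE),
               ll_grid, tolerance = 1e-4)
})

test_that("an empty zero class reduces the joint model to Poisson exactly", {
  coh <- small_cohort(n = 20, seed = 6, family = "poisson",
                      beta = c("(Intercept)" = 0.2, education_high = 0.4))
  dd <- build_design(coh, covariates = "education", waves = TRUE)
  beta <- c("(Intercept)" = 0.1, education_high = 0.3,
            waveT1 = 0, waveT2 = -0.1)
  spec_sep <- list(family = "twopart", zero_part = "inflation",
                   sharing = "separate", random = "intercept")
  pl_sep <- list(beta = beta, sd_intercept = 0.8,
                 beta_zero = c("(Intercept)" = 40, education_high = 0,
                               waveT1 = 0, waveT2 = 0))
  pl_pois <- list(beta = beta, sd_intercept = 0.8)
  expect_equal(agq_marginal_loglik(dd, pl_sep, spec_sep, n_quad = 15),
               agq_marginal_loglik(dd, pl_pois, spec1, n_quad = 15),
               tolerance = 1e-10)
})

test_that("log-likelihood is stable in the number of quadrature points", {
  coh <- small_cohort(n = 150, seed = 13)
  fit <- twopartmm(coh, family = "twopart", n_quad = 15)
  dd <- fit$design
  pl <- list(beta = coef(fit), sd_intercept = fit$vc$sd_intercept)
  ll15 <- agq_marginal_loglik(dd, pl, spec_tp, n_quad = 15)
  ll25 <- agq_marginal_loglik(dd, pl, spec_tp, n_quad = 25)
  expect_lt(abs(ll15 - ll25), 1e-3)
})
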