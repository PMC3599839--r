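test_that("poisson fit with no between-subject variance matches IRLS glm", {
  coh <- small_cohort(n = 250, seed = 17, family = "poisson",
                      beta = c("(Intercept)" = 0.3, education_high = 0.5,
                               waveT1 = -0.1, waveT2 = -0.2),
                      sd_intercept = 1e-10)
  fit <- twopartmm(coh, family = "poisson", n_quad = 11)
  df <- as.data.frame(coh)
  g <- glm(y ~ education + wave, data = df, family = poisson)
  expect_lt(max(abs(coef(fit) - coef(g))), 1e-3)
  expect_lt(fit$vc$sd_intercept, 0.05)
})

test_that("linear fit equals the ML linear mixed model oracle", {
  skip_if_not_installed("lme4")
  coh <- small_cohort(n = 150, seed = 9, family = "linear",
                      beta = c("(Intercept)" = 1, education_high = 0.8,
                               waveT1 = -0.2, waveT2 = -0.4),
                      sd_intercept = 0.9, sd_resid = 1.3)
  fit <- twopartmm(coh, family = "linear")
  g <- lme4::lmer(y ~ education + wave + (1 | subject),
                  data = as.data.frame(coh), REML = FALSE)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(g)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
  expect_equal(fit$vc$sd_resid, sigma(g), tolerance = 1e-3)
})

test_that("poisson AGQ fit matches glmer with the same quadrature", {
  skip_if_not_installed("lme4")
  coh <- small_cohort(n = 150, seed = 11, family = "poisson",
                      beta = c("(Intercept)" = 0.2, education_high = 0.5,
                               waveT1 = -0.1, waveT2 = -0.2),
                      sd_intercept = 0.8)
  fit <- twopartmm(coh, family = "poisson", n_quad = 15)
  g <- lme4::glmer(y ~ education + wave + (1 | subject),
                   data = as.data.frame(coh), family = poisson, nAGQ = 15)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(g)), tolerance = 1e-3)
  expect_equal(fit$vc$sd_intercept,
               sqrt(unname(unlist(lme4::VarCorr(g)))), tolerance = 1e-3)
  expect_equal(unname(fit$se[1:4]),
               unname(coef(summary(g))[, "Std. Error"]), tolerance = 1e-3)
})

test_that("standard errors track the analytic Fisher information", {
  coh <- small_cohort(n = 400, seed = 23, family = "poisson",
                      beta = c("(Intercept)" = 0.4, education_high = 0.5,
                               waveT1 = -0.1, waveT2 = -0.2),
                      sd_intercept = 1e-10)
  fit <- twopartmm(coh, family = "poisson", n_quad = 7)
  dd <- fit$design
  mu <- exp(drop(dd$X %*% coef(fit)))
  info <- t(dd$X) %*% (mu * dd$X)
  se_analytic <- sqrt(diag(solve(info)))
  expect_lt(max(abs(fit$se[1:4] / se_analytic - 1)), 0.05)
})

test_that("standard errors are stable under halving the difference step", {
  coh <- small_cohort(n = 100, seed = 31, family = "linear",
                      beta = c("(Intercept)" = 1, education_high = 0.6),
                      sd_intercept = 0.8, sd_resid = 1.2)
  f1 <- twopartmm(coh, family = "linear",
                  control = tpmm_control(se_step = 1e-4))
  f2 <- twopartmm(coh, family = "linear",
                  control = tpmm_control(se_step = 5e-5))
  expect_equal(f1$theta, f2$theta)  # same optimum, only the SE step differs
  expect_lt(max(abs(f1$se / f2$se - 1)), 1e-6)
})

test_that("Wald p-values are two-sided Gaussian in the reported z", {
  coh <- small_cohort(n = 120, seed = 5)
  fit <- twopartmm(coh, family = "twopart", n_quad = 9)
  expect_equal(unname(fit$p), unname(2 * pnorm(-abs(fit$z))))
  expect_true(all(fit$se[!is.na(fit$se)] > 0))
})

test_that("empirical-Bayes effects obey the closed-form linear shrinkage", {
  coh <- small_cohort(n = 120, seed = 19, family = "linear",
                      beta = c("(Intercept)" = 1, education_high = 0.7,
                               waveT1 = -0.3, waveT2 = -0.5),
                      sd_intercept = 1.1, sd_resid = 1.4)
  fit <- twopartmm(coh, family = "linear")
  dd <- fit$design
  resid <- dd$y - drop(dd$X %*% coef(fit))
  s2b <- fit$vc$sd_intercept^2
  s2e <- fit$vc$sd_resid^2
  for (s in c(1L, 7L, 42L)) {
    rows <- which(dd$subject_index == s)
    nj <- length(rows)
    lambda <- s2b / (s2b + s2e / nj)
    expect_equal(unname(fit$eb[s, 1L]), lambda * mean(resid[rows]),
                 tolerance = 1e-6)
  }
  # degenerate prior: with sd_intercept = 0 every posterior mean is 0
  coh0 <- small_cohort(n = 60, seed = 20, family = "poisson",
                       beta = c("(Intercept)" = 0.3, education_high = 0.4))
  dd0 <- build_design(coh0, covariates = "education", waves = TRUE)
  pl0 <- list(beta = c("(Intercept)" = 0.3, education_high = 0.4,
                       waveT1 = 0, waveT2 = 0), sd_intercept = 1e-12)
  ll <- agq_marginal_loglik(dd0, pl0,
                            list(family = "poisson", random = "intercept"),
                            n_quad = 7, eb = TRUE)
  expect_lt(max(abs(attr(ll, "eb"))), 1e-8)
})

test_that("EB effects of the count families average to about zero", {
  coh <- small_cohort(n = 600, seed = 29)
  fit <- twopartmm(coh, family = "twopart", n_quad = 9)
  expect_lt(abs(mean(fit$eb[, 1L])), 4 / sqrt(600))
})

test_that("an all-zero outcome under the two-part model flags a boundary", {
  d <- expand.grid(id = paste0("s", 1:20), t = c("T0", "T1"))
  d$y <- 0L
  ld <- longitudinal_data(d, "id", "t", "y")
  expect_no_error(fit <- twopartmm(ld, family = "twopart", n_quad = 5))
  expect_true(fit$boundary)
  expect_false(fit$converged)
  expect_true(all(is.na(fit$se)))
})

test_that("optimization improves on the fixed-effects starting values", {
  coh <- small_cohort(n = 100, seed = 37)
  fit <- twopartmm(coh, family = "twopart", n_quad = 9)
  dd <- fit$design
  spec <- fit$spec
  pl0 <- twopartmm:::start_values(dd, spec, NULL, tpmm_control())
  th0 <- twopartmm:::par_pack(pl0, spec)
  ll0 <- agq_marginal_loglik(dd, twopartmm:::par_unpack(th0, spec,
                                                        colnames(dd$X)),
                             spec, n_quad = 9)
  expect_gt(fit$loglik, ll0)
  expect_true(fit$converged)
})

test_that("BIC uses the requested sample-size convention", {
  coh <- small_cohort(n = 80, seed = 3)
  f_obs <- twopartmm(coh, family = "poisson", n_quad = 7, bic_n = "obs")
  f_sub <- twopartmm(coh, family = "poisson", n_quad = 7,
                     bic_n = "subjects")
  expect_equal(f_obs$bic, -2 * f_obs$loglik + f_obs$k * log(f_obs$n_obs))
  expect_equal(f_sub$bic,
               -2 * f_sub$loglik + f_sub$k * log(f_sub$n_subjects))
  expect_equal(BIC(f_obs), f_obs$bic)  # via the logLik method
})

test_that("predictions follow the family inverse links", {
  coh <- small_cohort(n = 60, seed = 41)
  fit <- twopartmm(coh, family = "twopart", n_quad = 7)
  eta <- predict(fit, type = "link")
  expect_equal(predict(fit), plogis(eta) * exp(eta))
  fitp <- twopartmm(coh, family = "poisson", n_quad = 7)
  expect_equal(predict(fitp), exp(predict(fitp, type = "link")))
  fitl <- twopartmm(coh, family = "linear")
  expect_equal(predict(fitl), predict(fitl, type = "link"))
  # residuals and the prediction table agree
  pt <- prediction_table(fit)
  expect_equal(pt$residual, pt$observed - pt$predicted)
  expect_equal(nrow(pt), fit$n_obs)
  expect_true(all(pt$predicted >= 0))
})

test_that("hurdle predictions use the zero-truncated mean", {
  coh <- small_cohort(n = 60, seed = 43, zero_part = "hurdle")
  fit <- twopartmm(coh, family = "twopart", zero_part = "hurdle",
                   n_quad = 7)
  eta <- predict(fit, type = "link")
  mu <- exp(eta)
  expect_equal(predict(fit), plogis(eta) * mu / (1 - exp(-mu)))
})

test_that("formula interface selects covariates and wave terms", {
  coh <- small_cohort(n = 60, seed = 2)
  f1 <- twopartmm(coh, y ~ education, family = "poisson", n_quad = 5)
  expect_identical(names(coef(f1)), c("(Intercept)", "education_high"))
  f2 <- twopartmm(coh, y ~ wave, family = "poisson", n_quad = 5)
  expect_identical(names(coef(f2)), c("(Intercept)", "waveT1", "waveT2"))
  expect_error(twopartmm(coh, y ~ nosuch, family = "poisson"),
               "not among declared covariates")
})

test_that("the fixed-effects mode reproduces glm and lm exactly", {
  coh <- small_cohort(n = 80, seed = 51)
  fp <- twopartmm(coh, family = "poisson", random = "none")
  g <- glm(y ~ education + wave, data = as.data.frame(coh),
           family = poisson)
  expect_equal(unname(coef(fp)), unname(coef(g)), tolerance = 1e-5)
  expect_equal(fp$loglik, as.numeric(logLik(g)), tolerance = 1e-7)
  expect_true(all(fp$eb == 0))
  fl <- twopartmm(coh, family = "linear", random = "none")
  o <- lm(y ~ education + wave, data = as.data.frame(coh))
  expect_equal(unname(coef(fl)), unname(coef(o)), tolerance = 1e-5)
  expect_equal(fl$loglik, as.numeric(logLik(o)), tolerance = 1e-6)
})
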