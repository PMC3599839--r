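#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defines the data-generating process of an observational cohort: a baseline
#' sample of subjects measured at a small number of waves, with monotone
#' dropout (once a subject leaves, it never returns), a binary education
#' indicator, subject-level Gaussian random effects, and count outcomes drawn
#' from one of the three model families at the shared linear predictor
#' \eqn{\eta_{ij} = x_{ij}'\beta + z_{ij}'b_j}.
#'
#' The defaults emulate the margins of the motivating diabetes cohort: 770
#' subjects at baseline over waves at 0/3/6 months with cumulative retention
#' (1, 0.80, 0.66), education prevalence 0.47, an education effect of 0.6 on
#' the shared predictor, random-intercept SD 1, and intercept/wave effects
#' calibrated so the population zero fraction declines from about 61.4% at
#' baseline to about 56.4% at six months. These are emulation targets for the
#' structure of such data, not a reconstruction of any real cohort.
#'
#' @param n_subjects Baseline cohort size.
#' @param waves Ordered wave labels.
#' @param time_values Numeric time per wave (months).
#' @param retention Cumulative probability of still being observed at each
#'   wave; first entry must be 1, entries non-increasing.
#' @param covariate_prev Prevalence of the high-education indicator.
#' @param beta Named fixed effects on the shared predictor, in design order
#'   (intercept, education dummy, wave dummies).
#' @param beta_zero Optional separate zero-part fixed effects (implies
#'   `sharing = "separate"`).
#' @param sd_intercept,sd_slope,rho Random-effect SDs and correlation.
#' @param sd_resid Residual SD (linear family only).
#' @param family,zero_part,random As in [twopartmm()].
#' @param seed Integer seed; identical configs give identical cohorts.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 770L,
                          waves = c("T0", "T1", "T2"),
                          time_values = c(0, 3, 6),
                          retention = c(1, 0.80, 0.66),
                          covariate_prev = 0.47,
                          beta = c("(Intercept)" = -0.203,
                                   education_high = 0.6,
                                   waveT1 = 0.162, waveT2 = 0.197),
                          beta_zero = NULL,
                          sd_intercept = 1.0, sd_slope = NULL, rho = 0,
                          sd_resid = NULL,
                          family = c("twopart", "poisson", "linear"),
                          zero_part = c("inflation", "hurdle"),
                          random = NULL,
                          seed = 1L) {
  family <- match.arg(family)
  zero_part <- match.arg(zero_part)
  if (is.null(random))
    random <- if (is.null(sd_slope)) "intercept" else "intercept_slope"
  if (length(retention) != length(waves))
    stop("retention must have one entry per wave", call. = FALSE)
  if (retention[1L] != 1 || any(diff(retention) > 0) ||
      any(retention < 0 | retention > 1))
    stop("retention must start at 1 and be non-increasing in [0, 1]",
         call. = FALSE)
  if (family == "linear" && is.null(sd_resid)) sd_resid <- 1
  if (random == "intercept_slope" && is.null(sd_slope))
    stop("random = 'intercept_slope' needs sd_slope", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), waves = waves,
                 time_values = time_values, retention = retention,
                 covariate_prev = covariate_prev, beta = beta,
                 beta_zero = beta_zero, sd_intercept = sd_intercept,
                 sd_slope = sd_slope, rho = rho, sd_resid = sd_resid,
                 family = family, zero_part = zero_part, random = random,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

coef_or_zero <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0

# Draw outcomes from the conditional distribution of a family at eta.
draw_family <- function(eta, spec, eta_zero = eta, sd_resid = NULL) {
  n <- length(eta)
  switch(spec$family,
    linear = stats::rnorm(n, eta, sd_resid),
    poisson = stats::rpois(n, exp(eta)),
    twopart = {
      nonzero <- stats::runif(n) < stats::plogis(eta_zero)
      y <- integer(n)
      mu <- exp(eta)
      if ((spec$zero_part %||% "inflation") == "inflation") {
        y[nonzero] <- stats::rpois(sum(nonzero), mu[nonzero])
      } else {
        # zero-truncated Poisson by inverse-cdf on the conditional scale
        idx <- which(nonzero)
        u <- stats::runif(length(idx))
        p0 <- exp(-mu[idx])
        y[idx] <- stats::qpois(p0 + u * (1 - p0), mu[idx])
        y[idx] <- pmax(y[idx], 1L)
      }
      y
    },
    stop("unknown family"))
}

#' Simulate a longitudinal cohort from a configured data-generating process
#'
#' Draws subject covariates and random effects, runs the configured model
#' family forward at each observed wave, and applies monotone dropout
#' independent of the outcome (missing completely at random). The result is
#' a validated [longitudinal_data()] object; the same configuration always
#' produces the identical cohort.
#'
#' @param config A [cohort_config()].
#' @return A `"longdata"` object with covariate `education` (levels
#'   `low`/`high`).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 50, seed = 42))
#' summarize_events(cohort, group_by = "education")
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  S <- config$n_subjects
  W <- length(config$waves)
  edu <- factor(ifelse(stats::runif(S) < config$covariate_prev,
                       "high", "low"), levels = c("low", "high"))
  spec <- list(family = config$family, zero_part = config$zero_part,
               random = config$random)
  L <- ranef_chol(list(sd_intercept = config$sd_intercept,
                       sd_slope = config$sd_slope, rho = config$rho), spec)
  b <- matrix(stats::rnorm(S * nrow(L)), S) %*% t(L)

  # monotone dropout: still observed at wave w with conditional probability
  # retention[w] / retention[w-1]
  observed <- matrix(TRUE, S, W)
  for (w in seq_len(W)[-1L]) {
    cond <- config$retention[w] / config$retention[w - 1L]
    stay <- stats::runif(S) < cond
    observed[, w] <- observed[, w - 1L] & stay
  }

  rows <- list()
  for (w in seq_len(W)) {
    idx <- which(observed[, w])
    if (!length(idx)) next
    x_edu <- as.numeric(edu[idx] == "high")
    wn <- paste0("wave", config$waves[w])
    eta <- coef_or_zero(config$beta, "(Intercept)") +
      coef_or_zero(config$beta, "education_high") * x_edu +
      coef_or_zero(config$beta, wn)
    zb <- b[idx, 1L]
    if (config$random == "intercept_slope") zb <- zb + b[idx, 2L] * (w - 1L)
    eta <- eta + zb
    eta_zero <- eta
    if (!is.null(config$beta_zero)) {
      eta_zero <- coef_or_zero(config$beta_zero, "(Intercept)") +
        coef_or_zero(config$beta_zero, "education_high") * x_edu +
        coef_or_zero(config$beta_zero, wn) + zb
    }
    y <- draw_family(eta, spec, eta_zero = eta_zero,
                     sd_resid = config$sd_resid)
    if (config$family == "linear") y <- pmax(0L, as.integer(round(y)))
    rows[[w]] <- data.frame(subject = sprintf("S%04d", idx),
                            wave = config$waves[w],
                            education = edu[idx], y = y,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$education <- factor(df$education, levels = c("low", "high"))
  longitudinal_data(df, subject = "subject", wave = "wave", outcome = "y",
                    covariates = "education", wave_levels = config$waves,
                    time_values = config$time_values)
}

#' Exact moments of the configured data-generating process
#'
#' For each wave-by-education cell integrates the conditional zero
#' probability and mean over the Gaussian random-effects distribution with a
#' high-order Gauss-Hermite rule, giving the population zero fraction and
#' mean count implied by a [cohort_config()]. Serves as the analytic oracle
#' for [simulate_cohort()].
#'
#' @param config A [cohort_config()].
#' @param n_quad Quadrature points (default 60).
#' @return A data.frame with one row per wave x education cell plus a
#'   marginal (`education = "all"`) row per wave: columns `wave`,
#'   `education`, `pr_zero`, `mean`.
#' @export
theoretical_moments <- function(config, n_quad = 60L) {
  stopifnot(inherits(config, "cohort_config"))
  rule <- gh_rule(n_quad)
  cell <- function(eta_fixed, wave_idx) {
    # integrate over b (intercept [+ slope * wave_idx])
    sd_eff <- if (config$random == "intercept_slope") {
      s1 <- config$sd_intercept; s2 <- config$sd_slope
      sqrt(s1^2 + (wave_idx * s2)^2 + 2 * config$rho * s1 * s2 * wave_idx)
    } else config$sd_intercept
    bnodes <- sqrt(2) * sd_eff * rule$nodes
    w <- rule$weights / sqrt(pi)
    eta <- eta_fixed + bnodes
    switch(config$family,
      linear = c(pr_zero = NA_real_, mean = sum(w * eta)),
      poisson = c(pr_zero = sum(w * exp(-exp(eta))),
                  mean = sum(w * exp(eta))),
      twopart = {
        pi2 <- stats::plogis(eta)
        mu <- exp(eta)
        if (config$zero_part == "inflation")
          c(pr_zero = sum(w * ((1 - pi2) + pi2 * exp(-mu))),
            mean = sum(w * pi2 * mu))
        else
          c(pr_zero = sum(w * (1 - pi2)),
            mean = sum(w * pi2 * mu / -expm1(-mu)))
      })
  }
  rows <- list()
  prev <- config$covariate_prev
  for (w in seq_along(config$waves)) {
    wn <- paste0("wave", config$waves[w])
    eta0 <- coef_or_zero(config$beta, "(Intercept)") +
      coef_or_zero(config$beta, wn)
    vals <- list(low = cell(eta0, w - 1L),
                 high = cell(eta0 + coef_or_zero(config$beta,
                                                 "education_high"),
                             w - 1L))
    vals$all <- (1 - prev) * vals$low + prev * vals$high
    for (e in names(vals))
      rows[[length(rows) + 1L]] <- data.frame(
        wave = config$waves[w], education = e,
        pr_zero = unname(vals[[e]]["pr_zero"]),
        mean = unname(vals[[e]]["mean"]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
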