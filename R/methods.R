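#' @export
print.twopartmm <- function(x, digits = 4, ...) {
  fam_label <- switch(x$spec$family,
    linear = "Linear mixed model",
    poisson = "Poisson mixed model",
    twopart = sprintf("Two-part joint mixed model (binomial/Poisson, %s, %s)",
                      x$spec$zero_part, x$spec$sharing))
  cat(fam_label, "\n")
  cat("Random effects:", x$spec$random, "| subjects:", x$n_subjects,
      "| observations:", x$n_obs, "\n")
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  if (!is.null(x$beta_zero)) {
    cat("Zero-part fixed effects:\n")
    print(round(x$beta_zero, digits))
  }
  if (!is.null(x$vc$sd_intercept))
    cat("Random-effect SD (intercept):", round(x$vc$sd_intercept, digits),
        "\n")
  if (!is.null(x$vc$sd_slope))
    cat("Random-effect SD (slope):", round(x$vc$sd_slope, digits),
        " corr:", round(x$vc$rho, digits), "\n")
  if (!is.null(x$vc$sd_resid))
    cat("Residual SD:", round(x$vc$sd_resid, digits), "\n")
  cat("logLik:", round(x$loglik, 3), "  BIC:", round(x$bic, 3), "\n")
  if (!x$converged) cat("NOT CONVERGED:", x$reason, "\n")
  if (x$boundary) cat("Boundary parameter(s):",
                      paste(x$boundary_pars, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a fitted model as a coefficient table
#'
#' @param object A fitted `"twopartmm"` model.
#' @param ... Unused.
#' @return An object of class `"summary.twopartmm"` carrying the coefficient
#'   table (`Coef.`, `Std. Err.`, `z`, `P > |z|`), variance components, BIC
#'   and convergence status.
#' @export
summary.twopartmm <- function(object, ...) {
  est <- natural_par_values(object$theta)
  tab <- data.frame(`Coef.` = est, `Std. Err.` = object$se,
                    z = object$z, `P > |z|` = object$p,
                    check.names = FALSE)
  structure(list(fit = object, coefficients = tab),
            class = "summary.twopartmm")
}

#' @export
print.summary.twopartmm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nCoefficient table (all free parameters):\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.twopartmm <- function(object, ...) object$coefficients

#' @export
vcov.twopartmm <- function(object, ...) object$vcov

#' @export
logLik.twopartmm <- function(object, ...) {
  structure(object$loglik, df = object$k,
            nobs = if (object$bic_n == "obs") object$n_obs
                   else object$n_subjects,
            class = "logLik")
}

#' @export
nobs.twopartmm <- function(object, ...) object$n_obs

#' Predicted outcome values from a fitted model
#'
#' Predictions at the subject level, including the empirical-Bayes random
#' effects by default: \eqn{\hat\eta_{ij} = x_{ij}'\hat\beta + z_{ij}'\hat
#' b_j}. The response-scale prediction is \eqn{\hat\eta} for the linear
#' family, \eqn{e^{\hat\eta}} for Poisson, \eqn{\hat\pi_2 e^{\hat\eta}} for
#' the two-part inflation model and \eqn{\hat\pi_2 \hat\mu/(1-e^{-\hat\mu})}
#' for the hurdle variant.
#'
#' @param object A fitted `"twopartmm"` model.
#' @param newdata Optional `"longdata"` with the same wave set and covariates
#'   as the training data; empirical-Bayes effects are recomputed for its
#'   subjects under the fitted parameters. Defaults to the training data.
#' @param type `"response"` (expected outcome) or `"link"` (linear
#'   predictor).
#' @param include_ranef Include the empirical-Bayes random effects (default
#'   `TRUE`); `FALSE` gives fixed-effects-only (marginal, b = 0) predictions.
#' @param ... Unused.
#' @return Numeric vector aligned with the rows of the data.
#' @export
predict.twopartmm <- function(object, newdata = NULL,
                              type = c("response", "link"),
                              include_ranef = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    dd <- object$design
    eb <- object$eb
  } else {
    stopifnot(inherits(newdata, "longdata"))
    if (!identical(levels(newdata$wave), levels(object$data$wave)))
      stop("newdata declares a different wave set than the training data",
           call. = FALSE)
    dd <- build_design(newdata, covariates = object$formula_terms$covariates,
                       waves = object$formula_terms$waves,
                       random = if (object$spec$random == "intercept_slope")
                         "intercept_slope" else "intercept")
    if (!identical(colnames(dd$X), colnames(object$design$X)))
      stop("newdata design does not match the fitted model (unseen ",
           "covariate level or missing column)", call. = FALSE)
    pl <- list(beta = object$coefficients, beta_zero = object$beta_zero,
               sd_intercept = object$vc$sd_intercept,
               sd_slope = object$vc$sd_slope, rho = object$vc$rho,
               sd_resid = object$vc$sd_resid)
    llf <- marginal_loglik(dd, pl, object$spec, eb = TRUE)
    eb <- attr(llf, "eb")
  }
  b <- if (include_ranef) eb else matrix(0, dd$n_subjects, ncol(dd$Z))
  zb <- rowSums(dd$Z * b[dd$subject_index, , drop = FALSE])
  eta <- drop(dd$X %*% object$coefficients) + zb
  if (type == "link") return(eta)
  eta_zero <- if (!is.null(object$beta_zero))
    drop(dd$X %*% object$beta_zero) + zb else eta
  family_mean(eta, object$spec$family,
              object$spec$zero_part %||% "inflation", eta_zero = eta_zero)
}

#' @export
fitted.twopartmm <- function(object, ...) predict(object)

#' @export
residuals.twopartmm <- function(object, ...) {
  object$design$y - predict(object)
}

#' Observed-vs-predicted table for model evaluation
#'
#' One row per record with the observed count, the prediction including the
#' empirical-Bayes random effects, and their difference — the basis of the
#' mean-squared-residual and zero-classification comparisons.
#'
#' @inheritParams predict.twopartmm
#' @param include_ranef Include empirical-Bayes effects in the predictions
#'   (default `TRUE`; `FALSE` gives marginal predictions).
#' @return A data.frame of class `"prediction_table"` with columns `subject`,
#'   `wave`, `observed`, `predicted`, `residual`.
#' @export
prediction_table <- function(object, newdata = NULL, include_ranef = TRUE) {
  stopifnot(inherits(object, "twopartmm"))
  dat <- if (is.null(newdata)) object$data else newdata
  pred <- predict(object, newdata = newdata, include_ranef = include_ranef)
  out <- data.frame(subject = dat$subject, wave = as.character(dat$wave),
                    observed = dat$y, predicted = as.numeric(pred),
                    residual = dat$y - as.numeric(pred),
                    stringsAsFactors = FALSE)
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Observed-vs-predicted scatter plot
#'
#' @param x A fitted `"twopartmm"` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.twopartmm <- function(x, ...) {
  pt <- prediction_table(x)
  graphics::plot(pt$predicted, pt$observed,
                 xlab = "Predicted", ylab = "Observed",
                 main = model_label(x), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(pt)
}

model_label <- function(fit) {
  base <- switch(fit$spec$family,
    linear = "Linear mixed",
    poisson = "Poisson mixed",
    twopart = "Two-part joint mixed (binomial/Poisson)")
  paste0(base, switch(fit$spec$random,
    intercept_slope = ", random intercept + slope",
    intercept = ", random intercept",
    none = ", fixed effects only"))
}

#' Simulate new outcomes from a fitted model
#'
#' Draws fresh random effects and outcomes on the design of the fitted data
#' (parametric-bootstrap style).
#'
#' @param object A fitted `"twopartmm"` model.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data.frame with `nsim` columns of simulated counts (or Gaussian
#'   outcomes for the linear family), rows aligned with the data.
#' @export
simulate.twopartmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dd <- object$design
  none <- identical(object$spec$random, "none")
  L <- if (!none)
    ranef_chol(list(sd_intercept = object$vc$sd_intercept,
                    sd_slope = object$vc$sd_slope, rho = object$vc$rho),
               object$spec)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    b <- if (none) matrix(0, dd$n_subjects, ncol(dd$Z))
         else matrix(stats::rnorm(dd$n_subjects * ncol(dd$Z)),
                     dd$n_subjects) %*% t(L)
    zb <- rowSums(dd$Z * b[dd$subject_index, , drop = FALSE])
    eta <- drop(dd$X %*% object$coefficients) + zb
    eta_zero <- if (!is.null(object$beta_zero))
      drop(dd$X %*% object$beta_zero) + zb else eta
    out[[s]] <- draw_family(eta, object$spec, eta_zero,
                            sd_resid = object$vc$sd_resid)
  }
  stats::setNames(as.data.frame(out), paste0("sim_", seq_len(nsim)))
}
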