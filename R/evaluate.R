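#' Bayesian information criterion
#'
#' \eqn{\mathrm{BIC} = -2 \ell + k \ln n}; lower indicates better fit after
#' penalizing the number of estimated parameters.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters, `>= 0`.
#' @param n Sample size, `>= 1`.
#' @return The BIC value.
#' @export
bic <- function(loglik, k, n) {
  stopifnot(k >= 0, n >= 1)
  -2 * loglik + k * log(n)
}

#' Mean squared residual of a prediction table
#'
#' @param pred A [prediction_table()] (or any data.frame with a `residual`
#'   column).
#' @return Mean of the squared observed-minus-predicted residuals.
#' @export
msr <- function(pred) {
  if (nrow(pred) == 0L) stop("empty prediction table", call. = FALSE)
  mean(pred$residual^2)
}

#' Percentage of observed zeros predicted as zero
#'
#' An observed zero counts as correctly predicted when its predicted expected
#' value falls below `threshold`; the default 0.5 is nearest-integer rounding
#' to zero.
#'
#' @param pred A [prediction_table()].
#' @param threshold Classification cut-off on the predicted value.
#' @return Percentage in `[0, 100]`.
#' @export
zero_accuracy <- function(pred, threshold = 0.5) {
  z <- pred$observed == 0
  if (!any(z)) stop("no observed zeros in the prediction table",
                    call. = FALSE)
  100 * sum(pred$predicted[z] < threshold) / sum(z)
}

#' Prevalence rate ratio of a log-link coefficient
#'
#' \eqn{e^{\beta}}, the multiplicative change in the expected event count per
#' unit of the covariate, with its percent-change reading
#' \eqn{100(e^{\beta} - 1)}. Displayed to two decimals.
#'
#' @param coef Coefficient(s) on the log scale.
#' @return A data.frame with columns `coef`, `ratio` (rounded to 2 decimals)
#'   and `pct_change`.
#' @examples
#' rate_ratio(0.66)  # ratio 1.93, a 93% higher rate
#' @export
rate_ratio <- function(coef) {
  ratio <- round(exp(coef), 2)
  data.frame(coef = coef, ratio = ratio, pct_change = 100 * (ratio - 1))
}

#' Decompose the marginal effect of a shared two-part coefficient
#'
#' For the shared-coefficient two-part inflation model the expected outcome
#' at linear predictor \eqn{\eta} is \eqn{E[y] = \pi_2(\eta) e^{\eta}}. The
#' derivative with respect to covariate \eqn{x_k} splits into two
#' interpretable pieces:
#' \deqn{\partial E[y]/\partial x_k =
#'   \underbrace{\pi_2 \mu \beta_k}_{\mathrm{count}} +
#'   \underbrace{\mu \pi_2 (1 - \pi_2) \beta_k}_{\mathrm{participation}}}
#' — the change in the count intensity among those above the limit, weighted
#' by the probability of being above it, plus the change in that probability,
#' weighted by the expected count.
#'
#' @param fit A fitted `"twopartmm"` model with `family = "twopart"`,
#'   `sharing = "shared"`, `zero_part = "inflation"`.
#' @param covariate Name of a fixed-effect coefficient in `coef(fit)`.
#' @param eta Evaluation point(s) for the linear predictor; default is the
#'   mean fitted linear predictor (including empirical-Bayes effects).
#' @return A data.frame with columns `eta`, `count_component`,
#'   `participation_component`, `total`.
#' @export
decompose_marginal_effect <- function(fit, covariate, eta = NULL) {
  stopifnot(inherits(fit, "twopartmm"))
  if (fit$spec$family != "twopart" ||
      !identical(fit$spec$sharing, "shared") ||
      !identical(fit$spec$zero_part, "inflation"))
    stop("decomposition is defined for the shared-coefficient two-part ",
         "inflation model only", call. = FALSE)
  if (!covariate %in% names(fit$coefficients))
    stop("unknown coefficient: ", covariate, call. = FALSE)
  beta_k <- fit$coefficients[[covariate]]
  if (is.null(eta)) eta <- mean(predict(fit, type = "link"))
  pi2 <- stats::plogis(eta)
  mu <- exp(eta)
  count_component <- pi2 * mu * beta_k
  participation_component <- mu * pi2 * (1 - pi2) * beta_k
  data.frame(eta = eta, count_component = count_component,
             participation_component = participation_component,
             total = count_component + participation_component)
}

#' Compare fitted models by BIC, MSR and zero-classification accuracy
#'
#' Assembles the comparison protocol for a set of models fitted to the same
#' dataset: BIC, mean squared residual of the empirical-Bayes predictions,
#' and the percentage of observed zeros predicted as zero, flagging the best
#' model under each criterion.
#'
#' @param fits A (optionally named) list of fitted `"twopartmm"` models on
#'   the same dataset.
#' @param threshold Zero-classification cut-off, see [zero_accuracy()].
#' @return A data.frame of class `"model_comparison"` with one row per model:
#'   `model`, `bic`, `msr`, `zero_accuracy`, `converged`, and logical
#'   `best_bic` / `best_msr` flags.
#' @export
compare_models <- function(fits, threshold = 0.5) {
  if (inherits(fits, "twopartmm")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "twopartmm")))
  n_obs <- vapply(fits, function(f) f$n_obs, 0)
  if (length(unique(n_obs)) != 1L)
    stop("models were fitted to datasets with different record counts",
         call. = FALSE)
  labels <- names(fits) %||% rep(NA_character_, length(fits))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    pt <- prediction_table(f)
    data.frame(
      model = if (!is.na(labels[i]) && nzchar(labels[i])) labels[i]
              else model_label(f),
      bic = f$bic, msr = msr(pt),
      zero_accuracy = if (any(pt$observed == 0)) zero_accuracy(pt, threshold)
                      else NA_real_,
      converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$best_bic <- out$bic == min(out$bic)
  out$best_msr <- out$msr == min(out$msr)
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat("Model comparison (lower BIC / MSR is better)\n")
  df <- as.data.frame(x)
  for (cc in c("bic", "msr", "zero_accuracy"))
    df[[cc]] <- round(df[[cc]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export an observed-vs-predicted scatter plot and its points
#'
#' Writes a PNG scatter of observed against predicted values with the
#' identity reference line, plus a CSV of the plotted points so the figure
#' can be rebuilt exactly.
#'
#' @param pred A [prediction_table()].
#' @param path Output path for the image (`.png`); the point table is written
#'   next to it with extension `.csv`.
#' @param main Plot title.
#' @return Invisibly, a character vector of the two files written.
#' @export
scatter_export <- function(pred, path, main = "Observed vs predicted") {
  stopifnot(nrow(pred) >= 1L)
  csv_path <- sub("\\.[a-zA-Z]+$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  ok <- tryCatch({
    grDevices::png(path, width = 720, height = 720, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(pred$predicted, pred$observed, xlab = "Predicted",
                   ylab = "Observed", main = main)
    graphics::abline(0, 1, lty = 2)
    TRUE
  }, error = function(e) {
    stop("could not write figure to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  utils::write.csv(as.data.frame(pred)[, c("observed", "predicted")],
                   csv_path, row.names = FALSE)
  invisible(c(path, csv_path))
}

#' Write a coefficient table in the three-column report layout
#'
#' Serializes a fitted model as a CSV with columns `Coef.`, `Std. Err.`,
#' `P > |z|` for each fixed effect, followed by variance components, BIC and
#' the convergence flag.
#'
#' @param fit A fitted `"twopartmm"` model.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coef_table <- function(fit, path) {
  s <- summary(fit)$coefficients
  df <- data.frame(parameter = rownames(s),
                   `Coef.` = round(s[["Coef."]], 4),
                   `Std. Err.` = round(s[["Std. Err."]], 4),
                   `P > |z|` = signif(s[["P > |z|"]], 4),
                   check.names = FALSE)
  extra <- data.frame(parameter = c("BIC", "logLik", "converged"),
                      `Coef.` = c(round(fit$bic, 4), round(fit$loglik, 4),
                                  as.numeric(fit$converged)),
                      `Std. Err.` = NA_real_, `P > |z|` = NA_real_,
                      check.names = FALSE)
  utils::write.csv(rbind(df, extra), path, row.names = FALSE, na = "")
  invisible(path)
}
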