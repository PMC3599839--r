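#' Control options for model fitting
#'
#' @param max_iter Maximum quasi-Newton iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param grad_step Finite-difference step for the numerical gradient.
#' @param se_step Base finite-difference step for the observed-information
#'   Hessian behind the standard errors.
#' @param boundary_tol Random-effect SDs below this are flagged as boundary
#'   estimates and their standard errors suppressed.
#' @param start_sd Starting value for every random-effect SD.
#' @return A list of class `"tpmm_control"`.
#' @export
tpmm_control <- function(max_iter = 500L, tol = 1e-8, grad_step = 1e-4,
                         se_step = 1e-4, boundary_tol = 1e-6,
                         start_sd = 0.5) {
  structure(list(max_iter = max_iter, tol = tol, grad_step = grad_step,
                 se_step = se_step, boundary_tol = boundary_tol,
                 start_sd = start_sd), class = "tpmm_control")
}

#' Fit a longitudinal mixed model for counts with excess zeros
#'
#' Fits one of three model families to a long-format longitudinal count
#' dataset by maximum marginal likelihood:
#' \describe{
#'   \item{`"linear"`}{Gaussian linear mixed model,
#'     \eqn{y_{ij} = x_{ij}'\beta + z_{ij}'b_j + \epsilon_{ij}} (closed-form
#'     marginal likelihood).}
#'   \item{`"poisson"`}{Poisson mixed model with log link,
#'     \eqn{y_{ij} \sim \mathrm{Pois}(e^{\eta_{ij}})}.}
#'   \item{`"twopart"`}{Two-part joint binomial/Poisson mixed model: a
#'     mixture of a point mass at zero (weight \eqn{\pi_1}, logit link) and a
#'     Poisson count part (mean \eqn{\mu}, log link) driven by one shared
#'     linear predictor \eqn{\eta_{ij} = x_{ij}'\beta + z_{ij}'b_j}, so each
#'     covariate gets a single coefficient governing both the chance of any
#'     event and how many.}
#' }
#' Random effects \eqn{b_j} (intercept, optionally plus a linear time slope)
#' are mean-zero Gaussian and are integrated out by adaptive Gauss-Hermite
#' quadrature for the count families. Standard errors come from the observed
#' information (central finite differences at the optimum, delta method back
#' to the natural scale); empirical-Bayes random effects are posterior means
#' under the fitted parameters.
#'
#' @param data A `"longdata"` object from [longitudinal_data()] or
#'   [read_long_table()].
#' @param formula Optional fixed-effects formula such as `y ~ education +
#'   wave`; the term `wave` stands for the baseline-reference wave dummies.
#'   When omitted, all declared covariates plus the wave dummies enter.
#' @param family `"twopart"`, `"poisson"` or `"linear"`.
#' @param random `"intercept"`, `"intercept_slope"` (random linear slope on
#'   the 0-based wave index), or `"none"` for the fixed-effects counterpart
#'   with every random-effect SD held at zero.
#' @param zero_part Two-part only: `"inflation"` (the Poisson component may
#'   also produce zeros) or `"hurdle"` (zero-truncated count part).
#' @param sharing Two-part only: `"shared"` (one coefficient vector for both
#'   parts, the joint model) or `"separate"` (own fixed effects for the zero
#'   part; random effects remain shared).
#' @param n_quad Quadrature points per random-effect dimension.
#' @param bic_n Sample size used in the BIC penalty: `"obs"` (subject-by-wave
#'   records, default) or `"subjects"`.
#' @param start Optional named list of starting values (`beta`,
#'   `sd_intercept`, `sd_slope`, `rho`, `sd_resid`, `beta_zero`).
#' @param control A [tpmm_control()] list.
#' @return An object of class `"twopartmm"`; see [summary.twopartmm()],
#'   [predict.twopartmm()], [prediction_table()].
#' @examples
#' cfg <- cohort_config(n_subjects = 120, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' fit <- twopartmm(cohort, y ~ education, family = "twopart", n_quad = 7)
#' summary(fit)
#' @export
twopartmm <- function(data, formula = NULL,
                      family = c("twopart", "poisson", "linear"),
                      random = c("intercept", "intercept_slope", "none"),
                      zero_part = c("inflation", "hurdle"),
                      sharing = c("shared", "separate"),
                      n_quad = 15L, bic_n = c("obs", "subjects"),
                      start = NULL, control = tpmm_control()) {
  stopifnot(inherits(data, "longdata"))
  family <- match.arg(family)
  random <- match.arg(random)
  zero_part <- match.arg(zero_part)
  sharing <- match.arg(sharing)
  bic_n <- match.arg(bic_n)
  if (n_quad < 1L) stop("n_quad must be >= 1", call. = FALSE)
  cl <- match.call()

  terms_ <- parse_fixed_formula(formula, data)
  dd <- build_design(data, covariates = terms_$covariates,
                     waves = terms_$waves,
                     random = if (random == "none") "intercept" else random)
  if (dd$n_subjects < 2L) stop("need at least 2 subjects", call. = FALSE)

  spec <- list(family = family, random = random,
               zero_part = if (family == "twopart") zero_part else NULL,
               sharing = if (family == "twopart") sharing else NULL,
               n_quad = as.integer(n_quad))

  degenerate_zeros <- family == "twopart" && all(dd$y == 0L)
  pl0 <- start_values(dd, spec, start, control)
  theta0 <- par_pack(pl0, spec)
  beta_names <- colnames(dd$X)
  cache <- new.env(parent = emptyenv())

  nll <- function(theta) {
    pl <- par_unpack(theta, spec, beta_names)
    ll <- tryCatch(marginal_loglik(dd, pl, spec, cache = cache),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  maxit <- if (degenerate_zeros) 25L else control$max_iter
  opt <- stats::optim(theta0, nll, method = "BFGS",
                      control = list(maxit = maxit,
                                     reltol = control$tol,
                                     ndeps = rep(control$grad_step,
                                                 length(theta0))))
  theta_hat <- opt$par
  pl_hat <- par_unpack(theta_hat, spec, beta_names)
  loglik <- -opt$value

  boundary <- logical(0)
  vc_names <- setdiff(names(theta_hat),
                      grep("^beta", names(theta_hat), value = TRUE))
  boundary_pars <- names(theta_hat)[startsWith(names(theta_hat), "log_sd") &
    exp(theta_hat) < control$boundary_tol]
  if (degenerate_zeros) boundary_pars <- names(theta_hat)

  converged <- opt$convergence == 0L && !degenerate_zeros
  reason <- if (degenerate_zeros)
    "boundary: all outcomes zero, the zero class absorbs all mass"
  else if (opt$convergence == 0L) "relative log-likelihood change below tol"
  else if (opt$convergence == 1L) "max_iter reached"
  else paste0("optim code ", opt$convergence, ": ", opt$message %||% "")

  se_info <- fit_standard_errors(nll, theta_hat, spec, beta_names,
                                 boundary_pars, control,
                                 converged = converged)

  k <- length(theta_hat)
  n_for_bic <- if (bic_n == "obs") length(dd$y) else dd$n_subjects
  bic_val <- bic(loglik, k, n_for_bic)

  llf <- marginal_loglik(dd, pl_hat, spec, eb = TRUE, cache = cache)
  eb <- attr(llf, "eb")
  rownames(eb) <- dd$subjects
  colnames(eb) <- colnames(dd$Z)

  structure(list(
    call = cl, spec = spec, data = data, design = dd,
    formula_terms = terms_,
    coefficients = pl_hat$beta, beta_zero = pl_hat$beta_zero,
    vc = list(sd_intercept = pl_hat$sd_intercept,
              sd_slope = pl_hat$sd_slope, rho = pl_hat$rho,
              sd_resid = pl_hat$sd_resid),
    theta = theta_hat, loglik = loglik, bic = bic_val, bic_n = bic_n,
    k = k, n_obs = length(dd$y), n_subjects = dd$n_subjects,
    se = se_info$se, vcov = se_info$vcov, z = se_info$z, p = se_info$p,
    converged = converged, reason = reason,
    boundary = length(boundary_pars) > 0L, boundary_pars = boundary_pars,
    eb = eb, opt = opt, control = control), class = "twopartmm")
}

parse_fixed_formula <- function(formula, data) {
  covs <- attr(data, "covariates")
  if (is.null(formula))
    return(list(covariates = covs, waves = TRUE))
  tl <- attr(stats::terms(formula), "term.labels")
  waves <- "wave" %in% tl
  covariates <- setdiff(tl, "wave")
  unknown <- setdiff(covariates, covs)
  if (length(unknown))
    stop("formula term(s) not among declared covariates: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  list(covariates = covariates, waves = waves)
}

# Fixed-effects-only starting values: OLS / IRLS Poisson, SDs at start_sd.
start_values <- function(dd, spec, start, control) {
  p <- ncol(dd$X)
  beta <- if (spec$family == "linear") {
    stats::coef(stats::lm.fit(dd$X, dd$y))
  } else if (all(dd$y == 0L)) {
    c(-3, rep(0, p - 1L))
  } else {
    stats::coef(stats::glm.fit(dd$X, dd$y, family = stats::poisson()))
  }
  beta[!is.finite(beta)] <- 0
  names(beta) <- colnames(dd$X)
  pl <- list(beta = beta,
             beta_zero = if (identical(spec$sharing, "separate")) beta,
             sd_intercept = if (spec$random != "none") control$start_sd,
             sd_slope = if (spec$random == "intercept_slope") control$start_sd,
             rho = if (spec$random == "intercept_slope") 0,
             sd_resid = if (spec$family == "linear")
               max(stats::sd(dd$y - drop(dd$X %*% beta)), 0.1))
  if (!is.null(start)) for (nm in names(start)) pl[[nm]] <- start[[nm]]
  pl
}

# Central-difference Hessian of fn at x with per-coordinate step h.
num_hessian <- function(fn, x, h) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  hh <- h * pmax(1, abs(x))
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, hh[i])
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / hh[i]^2
    if (i < p) for (j in seq((i + 1L), p)) {
      ej <- replace(numeric(p), j, hh[j])
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
           fn(x - ei - ej)) / (4 * hh[i] * hh[j])
    }
  }
  H
}

# Observed-information standard errors on the natural scale (delta method
# from the unconstrained parameterization).
fit_standard_errors <- function(nll, theta_hat, spec, beta_names,
                                boundary_pars, control, converged = TRUE) {
  p <- length(theta_hat)
  nat_names <- natural_par_names(theta_hat)
  empty <- list(se = stats::setNames(rep(NA_real_, p), nat_names),
                vcov = NULL,
                z = stats::setNames(rep(NA_real_, p), nat_names),
                p = stats::setNames(rep(NA_real_, p), nat_names))
  if (!converged && length(boundary_pars) == p) return(empty)
  H <- tryCatch(num_hessian(nll, theta_hat, control$se_step),
                error = function(e) NULL)
  if (is.null(H) || !all(is.finite(H))) {
    warning("Hessian could not be computed; standard errors unavailable")
    return(empty)
  }
  V <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(V)) {
    warning("observed information is not positive definite; ",
            "standard errors unavailable")
    return(empty)
  }
  # delta method: d(natural)/d(unconstrained) is diagonal
  jac <- rep(1, p)
  for (i in seq_len(p)) {
    nm <- names(theta_hat)[i]
    if (startsWith(nm, "log_sd")) jac[i] <- exp(theta_hat[i])
    if (nm == "atanh_rho") jac[i] <- 1 - tanh(theta_hat[i])^2
  }
  Vn <- diag(jac, p) %*% V %*% diag(jac, p)
  se <- sqrt(pmax(diag(Vn), 0))
  se[names(theta_hat) %in% boundary_pars] <- NA_real_
  est <- natural_par_values(theta_hat)
  z <- est / se
  pv <- 2 * stats::pnorm(-abs(z))
  dimnames(Vn) <- list(nat_names, nat_names)
  list(se = stats::setNames(se, nat_names), vcov = Vn,
       z = stats::setNames(z, nat_names), p = stats::setNames(pv, nat_names))
}

natural_par_names <- function(theta) {
  nm <- names(theta)
  nm <- sub("^log_sd", "sd", nm)
  sub("^atanh_rho$", "rho", nm)
}

natural_par_values <- function(theta) {
  v <- theta
  sel <- startsWith(names(theta), "log_sd")
  v[sel] <- exp(theta[sel])
  sel <- names(theta) == "atanh_rho"
  v[sel] <- tanh(theta[sel])
  stats::setNames(as.numeric(v), natural_par_names(theta))
}

#' Empirical-Bayes random effects of a fitted model
#'
#' Posterior means of the subject-specific random effects under the fitted
#' parameters (computed by the same adaptive quadrature as the likelihood;
#' closed form for the linear family).
#'
#' @param fit A fitted `"twopartmm"` model.
#' @return A subjects-by-effects numeric matrix.
#' @export
ranef_tpmm <- function(fit) {
  stopifnot(inherits(fit, "twopartmm"))
  fit$eb
}
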