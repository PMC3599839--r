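# Parameter handling ---------------------------------------------------------
#
# Free parameters are optimized on an unconstrained scale:
#   beta (and beta_zero under sharing = "separate") as-is,
#   SDs on the log scale, the intercept-slope correlation via atanh.
# par_pack / par_unpack are exact inverses.

par_pack <- function(pl, spec) {
  th <- pl$beta
  names(th) <- paste0("beta.", names(pl$beta))
  if (identical(spec$sharing, "separate") && spec$family == "twopart") {
    bz <- pl$beta_zero
    names(bz) <- paste0("beta_zero.", names(pl$beta))
    th <- c(th, bz)
  }
  if (spec$random == "none") {
    if (spec$family == "linear")
      th <- c(th, log_sd_resid = log(pl$sd_resid))
    return(th)
  }
  th <- c(th, log_sd_intercept = log(pl$sd_intercept))
  if (spec$random == "intercept_slope")
    th <- c(th, log_sd_slope = log(pl$sd_slope), atanh_rho = atanh(pl$rho))
  if (spec$family == "linear")
    th <- c(th, log_sd_resid = log(pl$sd_resid))
  th
}

par_unpack <- function(theta, spec, beta_names) {
  p <- length(beta_names)
  beta <- theta[seq_len(p)]
  names(beta) <- beta_names
  i <- p
  beta_zero <- NULL
  if (identical(spec$sharing, "separate") && spec$family == "twopart") {
    beta_zero <- theta[i + seq_len(p)]
    names(beta_zero) <- beta_names
    i <- i + p
  }
  if (spec$random == "none") {
    sd_resid <- if (spec$family == "linear") exp(theta[[i + 1L]]) else NULL
    return(list(beta = beta, beta_zero = beta_zero, sd_intercept = NULL,
                sd_slope = NULL, rho = NULL, sd_resid = sd_resid))
  }
  sd_intercept <- exp(theta[[i + 1L]]); i <- i + 1L
  sd_slope <- NULL; rho <- NULL
  if (spec$random == "intercept_slope") {
    sd_slope <- exp(theta[[i + 1L]])
    rho <- tanh(theta[[i + 2L]])
    i <- i + 2L
  }
  sd_resid <- if (spec$family == "linear") exp(theta[[i + 1L]]) else NULL
  list(beta = beta, beta_zero = beta_zero, sd_intercept = sd_intercept,
       sd_slope = sd_slope, rho = rho, sd_resid = sd_resid)
}

# Lower Cholesky factor of the random-effects covariance.
ranef_chol <- function(pl, spec) {
  if (spec$random == "intercept")
    matrix(pl$sd_intercept, 1L, 1L)
  else {
    s1 <- pl$sd_intercept; s2 <- pl$sd_slope; r <- pl$rho
    matrix(c(s1, s2 * r, 0, s2 * sqrt(max(0, 1 - r^2))), 2L, 2L)
  }
}

ranef_cov <- function(pl, spec) {
  L <- ranef_chol(pl, spec)
  L %*% t(L)
}

# Conditional log-likelihood -------------------------------------------------

#' Conditional log-likelihood of each subject given random-effect values
#'
#' Sums the family log-density over each subject's records at the linear
#' predictor \eqn{\eta_{ij} = x_{ij}'\beta + z_{ij}'b_j}. This is the
#' integrand of the marginal likelihood; it is exposed mainly for oracle
#' cross-checks of the quadrature.
#'
#' @param dd Design list from [build_design()].
#' @param pl Parameter list with `beta`, optional `beta_zero`, and `sd_resid`
#'   for the linear family.
#' @param b Matrix of random-effect values, one row per subject, one column
#'   per random effect (natural, not standardized, scale).
#' @param spec Model spec list with `family`, `zero_part`, `sharing`,
#'   `random`.
#' @return Numeric vector of per-subject log-likelihood contributions.
#' @keywords internal
#' @export
subject_conditional_loglik <- function(dd, pl, b, spec) {
  if (!is.matrix(b)) b <- matrix(b, nrow = dd$n_subjects)
  if (ncol(b) != ncol(dd$Z))
    stop("random-effect dimension mismatch: b has ", ncol(b),
         " column(s), Z has ", ncol(dd$Z), call. = FALSE)
  zb <- rowSums(dd$Z * b[dd$subject_index, , drop = FALSE])
  eta <- drop(dd$X %*% pl$beta) + zb
  eta_zero <- if (!is.null(pl$beta_zero)) drop(dd$X %*% pl$beta_zero) + zb
              else eta
  ll <- record_loglik(dd$y, eta, spec$family, spec$zero_part %||% "inflation",
                      sd_resid = pl$sd_resid, eta_zero = eta_zero)
  out <- numeric(dd$n_subjects)
  s <- rowsum(ll, dd$subject_index, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# Marginal log-likelihood, linear family (closed form) ------------------------
#
# Per subject y_j ~ N(X_j beta, Z_j Sigma Z_j' + sigma^2 I). Subjects sharing
# the same wave pattern share the covariance, so the Cholesky factor is
# computed once per pattern.
linear_marginal_loglik <- function(dd, pl, spec, per_subject = FALSE) {
  Sigma <- ranef_cov(pl, spec)
  s2 <- pl$sd_resid^2
  resid <- dd$y - drop(dd$X %*% pl$beta)
  rows_by_subj <- split(seq_len(nrow(dd$Z)), dd$subject_index)
  key <- vapply(rows_by_subj, function(r)
    paste(round(dd$Z[r, , drop = FALSE], 10), collapse = ","), "")
  ll <- numeric(dd$n_subjects)
  for (k in unique(key)) {
    subj <- which(key == k)
    r1 <- rows_by_subj[[subj[1L]]]
    Zp <- dd$Z[r1, , drop = FALSE]
    V <- Zp %*% Sigma %*% t(Zp) + diag(s2, length(r1))
    R <- tryCatch(chol(V), error = function(e)
      stop("singular residual covariance for subject ",
           dd$subjects[subj[1L]], call. = FALSE))
    E <- vapply(subj, function(s) resid[rows_by_subj[[s]]],
                numeric(length(r1)))
    E <- matrix(E, nrow = length(r1))
    W <- backsolve(R, E, transpose = TRUE)
    ll[subj] <- -0.5 * (length(r1) * log(2 * pi) +
                          2 * sum(log(diag(R))) + colSums(W^2))
  }
  if (per_subject) ll else sum(ll)
}

# Adaptive Gauss-Hermite quadrature ------------------------------------------

gh_rule <- function(n_quad) {
  statmod::gauss.quad(n_quad, kind = "hermite")
}

# Vectorized Newton search for the per-subject posterior mode in the
# standardized scale u (b = u L'). Returns list(U, H) where H holds the
# (negative-definite, clamped) per-subject Hessian of
# q(u) = conditional loglik + standard-normal log prior.
posterior_modes <- function(qfun, U0, d, tol = 1e-6, max_iter = 50L,
                            h = 1e-4) {
  U <- U0
  S <- nrow(U)
  ok <- FALSE
  if (d == 1L) {
    H <- rep(-1, S)
    for (it in seq_len(max_iter)) {
      f0 <- qfun(U)
      fp <- qfun(U + h)
      fm <- qfun(U - h)
      g <- (fp - fm) / (2 * h)
      g[!is.finite(g)] <- 0
      H <- pmin((fp - 2 * f0 + fm) / h^2, -1e-4)
      H[!is.finite(H)] <- -1
      step <- pmax(pmin(-g / H, 3), -3)
      U <- U + step
      if (max(abs(g)) < tol) { ok <- TRUE; break }
    }
    if (!all(is.finite(U))) return(NULL)
    list(U = U, H = matrix(H, S, 1L), ok = ok)
  } else {
    H11 <- H22 <- rep(-1, S); H12 <- rep(0, S)
    for (it in seq_len(max_iter)) {
      f0 <- qfun(U)
      fp1 <- qfun(sweep(U, 2, c(h, 0), "+")); fm1 <- qfun(sweep(U, 2, c(h, 0), "-"))
      fp2 <- qfun(sweep(U, 2, c(0, h), "+")); fm2 <- qfun(sweep(U, 2, c(0, h), "-"))
      fpp <- qfun(sweep(U, 2, c(h, h), "+")); fmm <- qfun(sweep(U, 2, c(h, h), "-"))
      fpm <- qfun(sweep(U, 2, c(h, -h), "+")); fmp <- qfun(sweep(U, 2, c(-h, h), "+"))
      g1 <- (fp1 - fm1) / (2 * h); g2 <- (fp2 - fm2) / (2 * h)
      g1[!is.finite(g1)] <- 0; g2[!is.finite(g2)] <- 0
      H11 <- (fp1 - 2 * f0 + fm1) / h^2
      H22 <- (fp2 - 2 * f0 + fm2) / h^2
      H12 <- (fpp - fpm - fmp + fmm) / (4 * h^2)
      H11[!is.finite(H11)] <- -1; H22[!is.finite(H22)] <- -1
      H12[!is.finite(H12)] <- 0
      # clamp each 2x2 Hessian to be negative definite (eigenvalue clamp)
      tr <- H11 + H22
      dif <- H11 - H22
      disc <- sqrt(pmax(dif^2 + 4 * H12^2, 0))
      lam1 <- (tr + disc) / 2; lam2 <- (tr - disc) / 2
      lam1c <- pmin(lam1, -1e-4); lam2c <- pmin(lam2, -1e-4)
      # reconstruct from (possibly clamped) eigen-decomposition
      theta_ang <- 0.5 * atan2(2 * H12, dif)
      ct <- cos(theta_ang); st <- sin(theta_ang)
      A11 <- lam1c * ct^2 + lam2c * st^2
      A22 <- lam1c * st^2 + lam2c * ct^2
      A12 <- (lam1c - lam2c) * ct * st
      det_ <- A11 * A22 - A12^2
      s1 <- -( A22 * g1 - A12 * g2) / det_
      s2 <- -(-A12 * g1 + A11 * g2) / det_
      nrm <- sqrt(s1^2 + s2^2)
      shrink <- ifelse(nrm > 3, 3 / nrm, 1)
      U <- U + cbind(s1 * shrink, s2 * shrink)
      H11 <- A11; H22 <- A22; H12 <- A12
      if (max(abs(c(g1, g2))) < tol) { ok <- TRUE; break }
    }
    if (!all(is.finite(U))) return(NULL)
    list(U = U, H = cbind(H11, H12, H22), ok = ok)
  }
}

#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Integrates each subject's conditional likelihood over the Gaussian
#' random-effects distribution. The integral is taken in the standardized
#' scale \eqn{b = L u}, \eqn{u \sim N(0, I)}: for each subject the posterior
#' mode of \eqn{u} is found by a damped Newton search, the Gauss-Hermite grid
#' is re-centered at the mode and re-scaled by the local curvature, and the
#' (tensor-product, for two random effects) quadrature sum is accumulated on
#' the log scale. If the mode search does not converge the rule falls back to
#' the non-adaptive grid (centered at 0, unit scale) with a warning.
#'
#' @inheritParams subject_conditional_loglik
#' @param n_quad Number of quadrature points per random-effect dimension.
#' @param per_subject Return the per-subject vector instead of the sum.
#' @param eb Also compute per-subject posterior means of the random effects.
#' @param cache Optional environment used to warm-start the mode search
#'   across successive calls during optimization.
#' @return The marginal log-likelihood (scalar, or per-subject vector), with
#'   attribute `"eb"` (subjects x effects matrix) when `eb = TRUE`.
#' @keywords internal
#' @export
agq_marginal_loglik <- function(dd, pl, spec, n_quad = spec$n_quad %||% 15L,
                                per_subject = FALSE, eb = FALSE,
                                cache = NULL) {
  d <- ncol(dd$Z)
  S <- dd$n_subjects
  L <- ranef_chol(pl, spec)
  qfun <- function(U) {
    if (!is.matrix(U)) U <- matrix(U, S, d)
    subject_conditional_loglik(dd, pl, U %*% t(L), spec) -
      0.5 * rowSums(U^2)
  }
  U0 <- if (!is.null(cache) && !is.null(cache$U) &&
            identical(dim(cache$U), c(S, d))) cache$U else matrix(0, S, d)
  mode_res <- posterior_modes(qfun, U0, d)
  if (is.null(mode_res)) {
    warning("posterior mode search failed; falling back to non-adaptive quadrature")
    mode_res <- list(U = matrix(0, S, d),
                     H = if (d == 1L) matrix(-1, S, 1L)
                         else cbind(rep(-1, S), 0, rep(-1, S)))
  }
  Uhat <- mode_res$U
  if (!is.null(cache)) cache$U <- Uhat

  rule <- gh_rule(n_quad)
  if (d == 1L) {
    a <- 1 / sqrt(-mode_res$H[, 1L])        # adaptive scale per subject
    log_det_A <- log(a)
    K <- n_quad
    M <- matrix(NA_real_, S, K)
    Unodes <- vector("list", K)
    for (k in seq_len(K)) {
      tk <- rule$nodes[k]
      Uk <- Uhat + sqrt(2) * a * tk
      M[, k] <- log(rule$weights[k]) + tk^2 + qfun(Uk)
      if (eb) Unodes[[k]] <- Uk
    }
  } else {
    # per-subject lower Cholesky of the adaptive covariance (-H)^{-1}
    H11 <- mode_res$H[, 1L]; H12 <- mode_res$H[, 2L]; H22 <- mode_res$H[, 3L]
    # (-H)^{-1} = adj(-H)/det(-H); det(-H) = det(H) in 2x2
    detH <- H11 * H22 - H12^2
    C11 <- -H22 / detH
    C22 <- -H11 / detH
    C12 <- H12 / detH
    l11 <- sqrt(pmax(C11, 1e-12))
    l21 <- C12 / l11
    l22 <- sqrt(pmax(C22 - l21^2, 1e-12))
    log_det_A <- log(l11) + log(l22)
    grid <- expand.grid(i = seq_len(n_quad), j = seq_len(n_quad))
    K <- nrow(grid)
    M <- matrix(NA_real_, S, K)
    Unodes <- vector("list", K)
    for (k in seq_len(K)) {
      t1 <- rule$nodes[grid$i[k]]; t2 <- rule$nodes[grid$j[k]]
      w <- rule$weights[grid$i[k]] * rule$weights[grid$j[k]]
      Uk <- Uhat + sqrt(2) * cbind(l11 * t1, l21 * t1 + l22 * t2)
      M[, k] <- log(w) + t1^2 + t2^2 + qfun(Uk)
      if (eb) Unodes[[k]] <- Uk
    }
  }
  mx <- apply(M, 1L, max)
  W <- exp(M - mx)
  sw <- rowSums(W)
  ll <- (d / 2) * log(2) + log_det_A - (d / 2) * log(2 * pi) + mx + log(sw)
  out <- if (per_subject) ll else sum(ll)
  if (eb) {
    EU <- matrix(0, S, d)
    for (k in seq_len(K)) {
      Uk <- Unodes[[k]]
      if (!is.matrix(Uk)) Uk <- matrix(Uk, S, d)
      EU <- EU + (W[, k] / sw) * Uk
    }
    attr(out, "eb") <- EU %*% t(L)
  }
  out
}

# Dispatch: marginal log-likelihood for any family.
marginal_loglik <- function(dd, pl, spec, per_subject = FALSE, eb = FALSE,
                            cache = NULL) {
  if (identical(spec$random, "none")) {
    out <- fixed_effects_loglik(dd, pl, spec, per_subject = per_subject)
    if (eb) attr(out, "eb") <- matrix(0, dd$n_subjects, ncol(dd$Z))
    return(out)
  }
  if (spec$family == "linear") {
    out <- linear_marginal_loglik(dd, pl, spec, per_subject = per_subject)
    if (eb) attr(out, "eb") <- linear_eb(dd, pl, spec)
    out
  } else {
    agq_marginal_loglik(dd, pl, spec, per_subject = per_subject, eb = eb,
                        cache = cache)
  }
}

# Closed-form empirical-Bayes (posterior mean) random effects, linear family:
# b_j = Sigma Z_j' V_j^{-1} (y_j - X_j beta).
linear_eb <- function(dd, pl, spec) {
  Sigma <- ranef_cov(pl, spec)
  s2 <- pl$sd_resid^2
  resid <- dd$y - drop(dd$X %*% pl$beta)
  rows_by_subj <- split(seq_len(nrow(dd$Z)), dd$subject_index)
  B <- matrix(0, dd$n_subjects, ncol(dd$Z))
  for (s in seq_len(dd$n_subjects)) {
    r <- rows_by_subj[[s]]
    Zp <- dd$Z[r, , drop = FALSE]
    V <- Zp %*% Sigma %*% t(Zp) + diag(s2, length(r))
    B[s, ] <- drop(Sigma %*% t(Zp) %*% solve(V, resid[r]))
  }
  B
}

# Fixed-effects counterpart (all random-effect SDs at zero): the
# conditional likelihood evaluated at b = 0.
fixed_effects_loglik <- function(dd, pl, spec, per_subject = FALSE) {
  ll <- subject_conditional_loglik(dd, pl, matrix(0, dd$n_subjects,
                                                  ncol(dd$Z)), spec)
  if (per_subject) ll else sum(ll)
}
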