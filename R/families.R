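#' Poisson log-probability with a degenerate point mass at mu = 0
#'
#' Thin validated wrapper around [stats::dpois()] that makes the boundary
#' convention explicit: at `mu = 0` the distribution is a point mass at zero,
#' so the log-probability is 0 for `y = 0` and `-Inf` for `y > 0`. That
#' degenerate case is the zero component of the two-part mixture.
#'
#' @param y Non-negative integer count(s).
#' @param mu Mean(s), `>= 0`.
#' @return Log-probability, recycled over the longer argument.
#' @export
poisson_logpmf <- function(y, mu) {
  if (any(y < 0) || any(y != round(y)))
    stop("y must be a non-negative integer", call. = FALSE)
  if (any(mu < 0)) stop("mu must be >= 0", call. = FALSE)
  stats::dpois(y, mu, log = TRUE)
}

#' Zero-truncated Poisson log-probability
#'
#' Log-probability of a Poisson count conditioned on being positive,
#' \eqn{\log[ \mathrm{Pois}(y;\mu) / (1 - e^{-\mu}) ]}. This is the count
#' component of the hurdle variant of the two-part model, which has no
#' support at zero.
#'
#' @param y Positive integer count(s).
#' @param mu Mean(s) of the untruncated Poisson, `> 0`.
#' @return Log-probability.
#' @export
truncated_poisson_logpmf <- function(y, mu) {
  if (any(y < 1) || any(y != round(y)))
    stop("y must be an integer >= 1 (the hurdle count part has no support at zero)",
         call. = FALSE)
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  # log(1 - exp(-mu)) via expm1 for small mu
  stats::dpois(y, mu, log = TRUE) - log(-expm1(-mu))
}

#' Shared-predictor link pair: logit for the zero part, log for the count part
#'
#' In the joint two-part model one linear predictor \eqn{\eta} drives both
#' parts: the probability of belonging to the non-zero class is
#' \eqn{\pi_2 = \mathrm{logit}^{-1}(\eta)} and the count mean is
#' \eqn{\mu = e^{\eta}}. The zero-class weight is \eqn{\pi_1 = 1 - \pi_2}.
#'
#' @param eta Finite linear predictor(s).
#' @return A list with components `pi2` and `mu`.
#' @examples
#' link_pair(0)   # pi2 = 0.5, mu = 1
#' @export
link_pair <- function(eta) {
  list(pi2 = stats::plogis(eta), mu = exp(eta))
}

#' Two-part binomial/Poisson log-probability at a shared linear predictor
#'
#' Evaluates the mixture
#' \deqn{\Pr(y) = \pi_1 \, g(y; 0) + \pi_2 \, g(y; \mu)}
#' where \eqn{g} is the Poisson pmf, \eqn{\pi_2 = \mathrm{logit}^{-1}(\eta_z)}
#' and \eqn{\mu = e^{\eta}}. Under the default shared coefficients the same
#' predictor feeds both links (`eta_zero = eta`); a separate zero-part
#' predictor may be supplied for the `sharing = "separate"` variant.
#'
#' Two zero-part forms are supported: `"inflation"` (the Poisson component can
#' itself produce zeros, the mixture exactly as written above) and `"hurdle"`
#' (all zeros come from the zero class and the count part is zero-truncated).
#'
#' @param y Non-negative integer count(s).
#' @param eta Linear predictor for the count part (log link).
#' @param zero_part `"inflation"` or `"hurdle"`.
#' @param eta_zero Linear predictor for the zero part (logit link); defaults
#'   to `eta` (shared coefficients).
#' @return Log-probability, computed overflow-safely on the log scale.
#' @export
twopart_logpmf <- function(y, eta, zero_part = c("inflation", "hurdle"),
                           eta_zero = eta) {
  zero_part <- match.arg(zero_part)
  if (any(y < 0) || any(y != round(y)))
    stop("y must be a non-negative integer", call. = FALSE)
  n <- max(length(y), length(eta), length(eta_zero))
  y <- rep_len(y, n); eta <- rep_len(eta, n); eta_zero <- rep_len(eta_zero, n)
  log_pi2 <- stats::plogis(eta_zero, log.p = TRUE)
  log_pi1 <- stats::plogis(-eta_zero, log.p = TRUE)
  mu <- exp(eta)
  out <- numeric(n)
  z <- y == 0L
  if (zero_part == "inflation") {
    if (any(z)) {
      # log(pi1 + pi2 * exp(-mu)) by log-sum-exp
      a <- log_pi1[z]
      b <- log_pi2[z] - mu[z]
      m <- pmax(a, b)
      out[z] <- m + log(exp(a - m) + exp(b - m))
    }
    if (any(!z))
      out[!z] <- log_pi2[!z] + stats::dpois(y[!z], mu[!z], log = TRUE)
  } else {
    out[z] <- log_pi1[z]
    if (any(!z))
      out[!z] <- log_pi2[!z] + truncated_poisson_logpmf(y[!z], mu[!z])
  }
  out
}

# Expected value of the outcome given the linear predictor(s), per family.
family_mean <- function(eta, family, zero_part = "inflation",
                        eta_zero = eta) {
  switch(family,
    linear = eta,
    poisson = exp(eta),
    twopart = {
      mu <- exp(eta)
      pi2 <- stats::plogis(eta_zero)
      if (zero_part == "inflation") pi2 * mu
      else ifelse(mu > 0, pi2 * mu / -expm1(-mu), pi2 * 1)
    },
    stop("unknown family: ", family))
}

# Per-record conditional log-density given the linear predictor(s).
# The predictor is clamped to +/- 30 for the count families so extreme
# trial values during optimization stay finite (exp(30) ~ 1e13).
record_loglik <- function(y, eta, family, zero_part = "inflation",
                          sd_resid = NULL, eta_zero = eta) {
  if (family != "linear") {
    eta <- pmin(pmax(eta, -30), 30)
    eta_zero <- pmin(pmax(eta_zero, -30), 30)
  }
  switch(family,
    linear = stats::dnorm(y, mean = eta, sd = sd_resid, log = TRUE),
    poisson = stats::dpois(y, exp(eta), log = TRUE),
    twopart = twopart_logpmf(y, eta, zero_part, eta_zero = eta_zero),
    stop("unknown family: ", family))
}
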