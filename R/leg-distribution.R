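## Core probability functions of the long-term exponential-geometric (LEG)
## model.  Latent cause count M ~ Geometric(p) on {0, 1, 2, ...} with
## P(M = m) = p (1-p)^m; given M = m >= 1 the event time is the minimum of m
## iid Exponential(lambda) activation times, i.e. Exponential(m * lambda);
## M = 0 means cured (infinite event time).  Marginalising M gives
##   S_pop(t) = p / (1 - (1-p) exp(-lambda t)).

#' Cure probability under the logistic link
#'
#' Computes \eqn{p = 1 / (1 + e^{-x'\beta})}, the probability that a subject
#' with covariate row `x` carries zero latent causes (is cured).
#' `exp(beta[j])` is therefore the odds ratio of being cured per unit
#' increase in covariate `j`.
#'
#' @param x Numeric covariate vector, or a matrix with one row per subject
#'   (first column conventionally the intercept).
#' @param beta Numeric coefficient vector of the same length as `x` (or as
#'   `ncol(x)`).
#' @return Cure probabilities in (0, 1), one per subject.
#' @examples
#' cure_probability(1, 0)       # 0.5
#' cure_probability(1, 0.579)   # ~0.641
#' @export
cure_probability <- function(x, beta) {
  if (is.matrix(x)) {
    if (ncol(x) != length(beta))
      stop("dimension mismatch: design has ", ncol(x), " columns but beta has length ",
           length(beta))
    eta <- drop(x %*% beta)
  } else {
    if (length(x) != length(beta))
      stop("dimension mismatch: x has length ", length(x), " but beta has length ",
           length(beta))
    eta <- sum(x * beta)
  }
  plogis(eta)
}

check_leg_args <- function(t, p, lambda, allow_p1 = TRUE) {
  if (any(t < 0)) stop("t must be non-negative")
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  if (!allow_p1 && any(p == 1)) stop("p must lie in (0, 1)")
  if (any(lambda <= 0)) stop("lambda must be positive")
  invisible(TRUE)
}

#' Population survival, density and hazard of the LEG model
#'
#' `leg_survival()` evaluates
#' \eqn{S_{pop}(t) = p / (1 - (1-p) e^{-\lambda t})}, which starts at 1 and
#' decreases to the cure fraction \eqn{p} as \eqn{t \to \infty}.
#' `leg_density()` is its negative derivative
#' \eqn{f_{pop}(t) = \lambda p (1-p) e^{-\lambda t} / (1 - (1-p) e^{-\lambda t})^2},
#' an improper density integrating to \eqn{1 - p}.  `leg_hazard()` is their
#' ratio.  Arguments recycle as usual.
#'
#' @param t Time since diagnosis, in days (non-negative).
#' @param p Cure probability in (0, 1]; `p = 1` is admitted (everyone cured,
#'   survival identically 1, density 0).
#' @param lambda Activation rate of a single latent cause, per day.
#' @return Numeric vector of survival probabilities, densities (per day), or
#'   hazards (per day).
#' @examples
#' leg_survival(1000, p = 0.5, lambda = 0.001)  # 0.6127
#' @export
leg_survival <- function(t, p, lambda) {
  check_leg_args(t, p, lambda)
  ## denominator written as p + (1-p)(1 - e^{-lambda t}) for stability near 0
  p / (p + (1 - p) * -expm1(-lambda * t))
}

#' @rdname leg_survival
#' @export
leg_density <- function(t, p, lambda) {
  check_leg_args(t, p, lambda)
  denom <- p + (1 - p) * -expm1(-lambda * t)
  lambda * p * (1 - p) * exp(-lambda * t) / denom^2
}

#' @rdname leg_survival
#' @export
leg_hazard <- function(t, p, lambda) {
  leg_density(t, p, lambda) / leg_survival(t, p, lambda)
}

#' Right-censored log-likelihood of the LEG model
#'
#' Evaluates, in the log domain throughout,
#' \deqn{\ell = \sum_i \delta_i \log f_{pop}(t_i; p_i, \lambda)
#'            + (1-\delta_i) \log S_{pop}(t_i; p_i, \lambda)}
#' with per-subject cure probability \eqn{p_i = logit^{-1}(x_i'\beta)}.
#' Extreme linear predictors are handled through `plogis(log.p = TRUE)`
#' rather than forming \eqn{e^{x'\beta}} directly.
#'
#' @param time Follow-up times in days.
#' @param event Event indicators (1 = event, 0 = right-censored).
#' @param X Design matrix (intercept included), one row per subject.
#' @param beta Cure-logit coefficients, length `ncol(X)`.
#' @param log_lambda Natural log of the exponential activation rate (per day).
#' @return The log-likelihood (a finite scalar whenever every event record
#'   has cure probability < 1).
#' @export
leg_loglik <- function(time, event, X, beta, log_lambda) {
  if (any(time < 0)) stop("time must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  if (nrow(X) != length(time) || length(event) != length(time))
    stop("design rows must align with records")
  if (ncol(X) != length(beta))
    stop("dimension mismatch: design has ", ncol(X), " columns but beta has length ",
         length(beta))
  lambda <- exp(log_lambda)
  eta <- drop(X %*% beta)
  log_p <- plogis(eta, log.p = TRUE)     # log p, safe for eta << 0
  log_q <- plogis(-eta, log.p = TRUE)    # log (1-p), safe for eta >> 0
  p <- exp(log_p)
  u <- -expm1(-lambda * time)            # 1 - e^{-lambda t}
  log_D <- log(p + exp(log_q) * u)       # log denominator, in (log p, 0]
  ev <- event == 1
  if (any(ev & log_q == -Inf))
    stop("event recorded for a subject with cure probability 1; likelihood is -Inf")
  ll <- numeric(length(time))
  ll[!ev] <- log_p[!ev] - log_D[!ev]
  ll[ev] <- log_lambda + log_p[ev] + log_q[ev] - lambda * time[ev] - 2 * log_D[ev]
  out <- sum(ll)
  if (is.nan(out)) stop("log-likelihood evaluated to NaN; check inputs")
  out
}

## Analytic gradient of leg_loglik with respect to (beta, log_lambda).
## Used by the optimizer and finite-differenced for the observed information.
leg_loglik_grad <- function(time, event, X, beta, log_lambda) {
  lambda <- exp(log_lambda)
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  q <- 1 - p
  e_lt <- exp(-lambda * time)
  u <- -expm1(-lambda * time)
  D <- p + q * u
  ev <- event == 1
  mult <- ifelse(ev, 2, 1)               # D enters squared in the density
  ## d ell_i / d p  (the 1/p - 1/(1-p) event term combined with dD/dp = 1-u)
  dl_dp <- 1 / p - mult * (1 - u) / D
  dl_dp[ev] <- dl_dp[ev] - 1 / q[ev]
  dl_deta <- dl_dp * p * q
  ## d ell_i / d lambda, then chain rule to log_lambda
  dD_dlam <- q * time * e_lt
  dl_dlam <- -mult * dD_dlam / D
  dl_dlam[ev] <- dl_dlam[ev] + 1 / lambda - time[ev]
  c(drop(crossprod(X, dl_deta)), sum(dl_dlam) * lambda)
}
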