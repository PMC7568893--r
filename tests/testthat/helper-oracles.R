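## Independent oracles, deliberately naive: they re-derive quantities the
## package computes in closed form, by explicit marginalization or
## brute-force recomputation, and are only ever run on tiny inputs.

## LEG log-likelihood by explicit truncated-series marginalization of the
## latent cause count M: S(t) = sum_m p q^m e^{-m lambda t},
## f(t) = sum_{m>=1} p q^m m lambda e^{-m lambda t}.
series_loglik <- function(time, event, X, beta, log_lambda, m_max = 500) {
  lambda <- exp(log_lambda)
  p <- plogis(drop(X %*% beta))
  q <- 1 - p
  m <- 0:m_max
  ll <- 0
  for (i in seq_along(time)) {
    w <- p[i] * q[i]^m * exp(-m * lambda * time[i])
    if (event[i] == 1) {
      ll <- ll + log(sum(w * m * lambda))
    } else {
      ll <- ll + log(sum(w))
    }
  }
  ll
}

## Kaplan-Meier by brute-force risk-set recomputation (deaths precede
## censorings at ties: subjects censored at t are still at risk at t).
brute_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  surv <- numeric(length(ut))
  s <- 1
  gw <- 0
  se <- numeric(length(ut))
  for (j in seq_along(ut)) {
    n_j <- sum(times >= ut[j])
    d_j <- sum(times == ut[j] & events == 1)
    s <- s * (1 - d_j / n_j)
    gw <- gw + if (n_j > d_j) d_j / (n_j * (n_j - d_j)) else Inf
    surv[j] <- s
    se[j] <- if (s > 0) s * sqrt(gw) else 0
  }
  data.frame(time = ut, survival = surv, std_err = se)
}

## A converged-looking fit object built directly from published-style
## (estimate, SE) pairs, for exercising the Wald reporting path alone.
fake_fit <- function(estimates, ses) {
  k <- length(estimates)
  V <- diag(c(ses^2, 0.01), k + 1)
  nm <- c(names(estimates), "log_lambda")
  dimnames(V) <- list(nm, nm)
  structure(list(
    coefficients = estimates, log_lambda = log(2e-4), lambda = 2e-4,
    vcov = V, loglik = -100, converged = TRUE, boundary = FALSE,
    n = 427L, n_events = 88L, n_censored = 339L,
    xlevels = list(diagnosis = c("ALL", "MM", "NHL", "HD", "AML"),
                   sex = c("female", "male"),
                   bmi_cat = c("Obese", "UW", "NW", "OW")),
    terms = NULL, call = NULL), class = "legcure")
}

## The published coefficient table used throughout the arithmetic checks.
published_rows <- function() {
  data.frame(
    term = c("diagnosisMM", "diagnosisAML", "diagnosisHD", "diagnosisNHL",
             "sexmale", "age_years", "hb_pre", "n_recurrence"),
    estimate = c(0.92, 1.21, 1.53, 0.52, -0.32, -0.09, 0.47, -0.68),
    se = c(0.37, 0.42, 0.53, 0.35, 0.44, 0.04, 0.23, 0.25),
    p_printed = c(0.01, 0.004, 0.004, 0.14, 0.47, 0.02, 0.04, 0.006),
    p_digits = c(2, 3, 3, 2, 2, 2, 2, 3),
    or_printed = c(2.51, 3.35, 4.62, 1.68, 0.73, 0.91, 1.6, 0.51))
}

## small reusable cohort fixture
small_cohort <- function(n = 200, seed = 42, ...) {
  generate_cohort(cohort_config(n = n, ...), seed = seed)
}

full_formula <- survival::Surv(time_days, event) ~ diagnosis + sex +
  bmi_cat + age_years + hb_pre + n_recurrence
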