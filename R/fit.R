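#' Fit a long-term exponential-geometric cure-rate model
#'
#' Maximum-likelihood fit of the LEG cure model: the left-hand side is a
#' [survival::Surv] object (time in days, event indicator), the right-hand
#' side specifies the covariates entering the cure logit.  The exponential
#' activation rate \eqn{\lambda} is a single global parameter; covariates
#' act only on the cure probability, so each `exp(coefficient)` is an odds
#' ratio of being cured.
#'
#' Optimization is quasi-Newton (BFGS) with an analytic gradient, started
#' deterministically (intercept at the logit of the Kaplan-Meier plateau,
#' other coefficients 0, \eqn{\lambda} at events / person-time among
#' events) plus `restarts` seeded jittered restarts; the best optimum wins.
#' The covariance matrix is the inverse of the observed information,
#' obtained by central finite differences of the analytic gradient
#' (relative step 1e-5) and symmetrized.
#'
#' @param formula A formula `Surv(time, event) ~ covariates`.
#' @param data A data frame containing the variables.
#' @param restarts Number of jittered restarts (default 4).
#' @param restart_sd Standard deviation of the Gaussian jitter applied to
#'   the starting point on the working scale.
#' @param restart_seed Seed for the (local, state-preserving) jitter stream.
#' @param control Passed to [stats::optim()] (with `fnscale` forced to -1).
#' @return An object of class `"legcure"` with components `coefficients`
#'   (cure-logit coefficients), `log_lambda`, `lambda`, `vcov` (covariance
#'   of `(beta, log_lambda)`), `loglik`, `converged`, `boundary`,
#'   `near_boundary` (`TRUE` when the maximizer sits on the
#'   weakly-identified `lambda -> 0` ridge where predicted cure
#'   probabilities collapse to 0 and the cure fraction is unidentified),
#'   `n`, `n_events`, `n_censored`, `xlevels`, `terms`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 300), seed = 1)
#' fit <- legcure(survival::Surv(time_days, event) ~ age_years, data = cohort)
#' summary(fit)
#' @export
legcure <- function(formula, data, restarts = 4, restart_sd = 0.5,
                    restart_seed = 1L, control = list()) {
  mf <- model.frame(formula, data = data, na.action = na.omit)
  y <- model.response(mf)
  if (!inherits(y, "Surv"))
    stop("the response must be a survival::Surv(time, event) object")
  time <- as.numeric(y[, "time"])
  event <- as.numeric(y[, "status"])
  mt <- attr(mf, "terms")
  X <- model.matrix(mt, mf)
  if (ncol(X) == 0) stop("the cure logit needs at least an intercept")

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  n_events <- sum(event == 1)
  k <- ncol(X)
  par_names <- c(colnames(X), "log_lambda")

  if (n_events == 0) {
    ## No events: the likelihood increases without bound as p -> 1 and
    ## lambda is unidentified.  Report the boundary rather than crash.
    beta <- setNames(rep(0, k), colnames(X))
    if ("(Intercept)" %in% colnames(X)) beta["(Intercept)"] <- Inf
    out <- structure(list(
      coefficients = beta, log_lambda = NA_real_, lambda = NA_real_,
      vcov = matrix(NA_real_, k + 1, k + 1, dimnames = list(par_names, par_names)),
      loglik = 0, converged = FALSE, boundary = TRUE,
      n = length(time), n_events = 0L, n_censored = length(time),
      xlevels = stats::.getXlevels(mt, mf), terms = mt,
      call = match.call(), optim = NULL), class = "legcure")
    return(out)
  }

  ## deterministic start
  km <- km_fit(time, event)
  plateau <- plateau_cure_fraction(km)$cure_fraction
  plateau <- min(max(plateau, 0.02), 0.98)
  beta0 <- rep(0, k)
  if ("(Intercept)" %in% colnames(X))
    beta0[match("(Intercept)", colnames(X))] <- qlogis(plateau)
  lambda0 <- n_events / sum(time[event == 1])
  start <- c(beta0, log(lambda0))

  negok <- function(par) {
    tryCatch(leg_loglik(time, event, X, par[seq_len(k)], par[k + 1]),
             error = function(e) -Inf)
  }
  grad <- function(par) leg_loglik_grad(time, event, X, par[seq_len(k)], par[k + 1])
  ctrl <- utils::modifyList(list(fnscale = -1, maxit = 1000, reltol = 1e-12),
                            control)

  starts <- list(start)
  if (restarts > 0) {
    jit <- with_preserved_seed(restart_seed, function()
      matrix(rnorm(restarts * (k + 1), sd = restart_sd), restarts))
    for (j in seq_len(restarts)) starts[[j + 1]] <- start + jit[j, ]
  }

  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, negok, gr = grad, method = "BFGS", control = ctrl),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value > best$value + 1e-10) best <- res
  }
  if (is.null(best)) stop("optimization failed from every starting point")

  par <- setNames(best$par, par_names)
  info <- observed_information(function(p) leg_loglik_grad(
    time, event, X, p[seq_len(k)], p[k + 1]), par)
  V <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, k + 1, k + 1))
  dimnames(V) <- list(par_names, par_names)
  converged <- best$convergence == 0 && all(is.finite(V)) && all(diag(V) > 0)

  ## cure models lose identifiability along the lambda -> 0, p -> 0 ridge,
  ## where the model degenerates to a heavy-tailed no-cure distribution;
  ## flag fits whose predicted cure probabilities have all collapsed
  p_hat <- plogis(drop(X %*% par[seq_len(k)]))
  near_boundary <- max(p_hat) < 1e-3

  structure(list(
    coefficients = par[seq_len(k)],
    log_lambda = unname(par[k + 1]), lambda = exp(unname(par[k + 1])),
    vcov = V, loglik = best$value,
    converged = converged, boundary = FALSE, near_boundary = near_boundary,
    n = length(time), n_events = as.integer(n_events),
    n_censored = as.integer(length(time) - n_events),
    xlevels = stats::.getXlevels(mt, mf), terms = mt,
    call = match.call(), optim = best), class = "legcure")
}

## - log-likelihood Hessian via central differences of the analytic
##   gradient; relative step 1e-5, symmetrized.  Returns the observed
##   information (negative Hessian).
observed_information <- function(grad_fn, par, rel_step = 1e-5) {
  k <- length(par)
  H <- matrix(0, k, k)
  h <- rel_step * pmax(abs(par), 1)
  for (j in seq_len(k)) {
    up <- dn <- par
    up[j] <- par[j] + h[j]
    dn[j] <- par[j] - h[j]
    H[, j] <- (grad_fn(up) - grad_fn(dn)) / (2 * h[j])
  }
  -(H + t(H)) / 2
}

## Run fn() under a fixed seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' @export
print.legcure <- function(x, digits = 4, ...) {
  cat("Long-term exponential-geometric cure-rate model\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  cat(sprintf("n = %d (%d events, %d censored)\n", x$n, x$n_events, x$n_censored))
  if (x$boundary) {
    cat("Boundary fit: no events observed; cure probability -> 1, lambda unidentified.\n")
    return(invisible(x))
  }
  cat("\nCure-logit coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nlambda = %.6g per day  (log lambda = %.4f)\n", x$lambda, x$log_lambda))
  cat(sprintf("log-likelihood = %.3f%s\n", x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (isTRUE(x$near_boundary))
    cat("Note: fit lies near the no-cure boundary (lambda -> 0, cure",
        "probabilities ~ 0);\nthe cure fraction is not identified for",
        "these data.\n")
  invisible(x)
}

#' @export
coef.legcure <- function(object, ...) object$coefficients

#' @export
vcov.legcure <- function(object, ...) object$vcov

#' @export
logLik.legcure <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            nobs = object$n, class = "logLik")
}

#' Wald summary table for a LEG cure model
#'
#' One row per cure-logit coefficient: estimate, standard error, z, two-sided
#' normal p-value, odds ratio of being cured `exp(estimate)` and its Wald
#' confidence interval `exp(estimate +/- z_{a/2} SE)`.  Full precision is
#' retained in the returned table; the print method rounds odds ratios and
#' interval bounds to 2 decimals and stars p-values at the 0.05 level.
#'
#' @param object A converged `"legcure"` fit.
#' @param level Confidence level, default 0.95.
#' @param ... Unused.
#' @return An object of class `"summary.legcure"`; its `$table` is a data
#'   frame with columns term, estimate, se, z, p_value, odds_ratio, ci_low,
#'   ci_high, significant.
#' @export
summary.legcure <- function(object, level = 0.95, ...) {
  if (!object$converged)
    stop("fit did not converge; inspect $optim and $boundary before summarising")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  est <- object$coefficients
  se <- sqrt(diag(object$vcov)[seq_along(est)])
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  zq <- qnorm(1 - (1 - level) / 2)
  tab <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    z = unname(z), p_value = unname(p),
    odds_ratio = exp(unname(est)),
    ci_low = exp(unname(est - zq * se)),
    ci_high = exp(unname(est + zq * se)),
    significant = unname(p <= 0.05),
    row.names = NULL)
  structure(list(table = tab, level = level,
                 lambda = object$lambda,
                 lambda_se = object$lambda * sqrt(diag(object$vcov)["log_lambda"]),
                 loglik = object$loglik, n = object$n,
                 n_events = object$n_events, call = object$call),
            class = "summary.legcure")
}

#' @export
print.summary.legcure <- function(x, ...) {
  cat("LEG cure-rate model: Wald summary (odds ratios of being cured)\n")
  cat(sprintf("n = %d, events = %d, log-likelihood = %.3f\n\n",
              x$n, x$n_events, x$loglik))
  tab <- x$table
  shown <- data.frame(
    term = tab$term,
    estimate = sprintf("%.2f", tab$estimate),
    se = sprintf("%.2f", tab$se),
    p_value = format_pvalue(tab$p_value),
    OR = sprintf("%.2f", tab$odds_ratio),
    ci = sprintf("(%.2f, %.2f)", tab$ci_low, tab$ci_high))
  names(shown)[6] <- sprintf("%g%% CI", 100 * x$level)
  print(shown, row.names = FALSE, right = FALSE)
  cat(sprintf("\nlambda = %.3g per day (SE %.2g)\n", x$lambda, x$lambda_se))
  invisible(x)
}

## larger of 3 decimals or 2 significant figures, star at p <= 0.05
format_pvalue <- function(p) {
  txt <- vapply(p, function(pi) {
    if (pi >= 0.001) sprintf("%.3g", round(pi, 3)) else sprintf("%.2g", pi)
  }, character(1))
  paste0(txt, ifelse(p <= 0.05, "*", ""))
}

#' Pairwise contrast between two levels of a fitted factor
#'
#' Wald inference for the cure odds ratio of `level_a` relative to
#' `level_b` within the same factor, `exp(beta_a - beta_b)`, with variance
#' `var(beta_a) + var(beta_b) - 2 cov(beta_a, beta_b)`.  Either level may be
#' the factor's reference category (coefficient 0).
#'
#' @param object A converged `"legcure"` fit.
#' @param factor_name Name of the factor as used in the model formula.
#' @param level_a,level_b Factor levels to contrast.
#' @param level Confidence level.
#' @return A one-row data frame: estimate (log scale), se, z, p_value,
#'   odds_ratio, ci_low, ci_high.
#' @export
pairwise_contrast <- function(object, factor_name, level_a, level_b,
                              level = 0.95) {
  if (!object$converged) stop("fit did not converge")
  lv <- object$xlevels[[factor_name]]
  if (is.null(lv))
    stop("unknown factor '", factor_name, "'; fitted factors: ",
         paste(names(object$xlevels), collapse = ", "))
  for (l in c(level_a, level_b))
    if (!l %in% lv)
      stop("unknown level '", l, "'; valid levels: ", paste(lv, collapse = ", "))
  k <- length(object$coefficients)
  contrast_vec <- function(l) {
    v <- setNames(numeric(k), names(object$coefficients))
    nm <- paste0(factor_name, l)
    if (nm %in% names(v)) v[nm] <- 1     # reference level contributes 0
    v
  }
  cv <- contrast_vec(level_a) - contrast_vec(level_b)
  est <- sum(cv * object$coefficients)
  se <- sqrt(drop(t(cv) %*% object$vcov[seq_len(k), seq_len(k)] %*% cv))
  z <- if (se == 0) 0 else est / se
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(
    level_a = level_a, level_b = level_b,
    estimate = est, se = se, z = z, p_value = 2 * pnorm(-abs(z)),
    odds_ratio = exp(est), ci_low = exp(est - zq * se),
    ci_high = exp(est + zq * se), row.names = NULL)
}

#' Predictions from a LEG cure model
#'
#' @param object A converged `"legcure"` fit.
#' @param newdata Optional data frame of covariates; predictions require the
#'   covariates used at fit time (set `type = "cure"` on the fitting data to
#'   reproduce per-subject cure probabilities).
#' @param type `"cure"` for per-subject cure probabilities, `"link"` for the
#'   cure-logit linear predictor, `"survival"` for population survival at
#'   `times`.
#' @param times Horizon(s) in days, required for `type = "survival"`.
#' @param ... Unused.
#' @return For `"cure"` and `"link"`, a numeric vector; for `"survival"`, a
#'   matrix with one row per subject and one column per horizon.
#' @export
predict.legcure <- function(object, newdata = NULL,
                            type = c("cure", "link", "survival"),
                            times = NULL, ...) {
  type <- match.arg(type)
  if (object$boundary) stop("boundary fit: predictions are degenerate (p = 1)")
  tt <- delete.response(object$terms)
  if (is.null(newdata))
    stop("supply `newdata` (the fitting data or new covariate rows)")
  mf <- model.frame(tt, newdata, xlev = object$xlevels, na.action = na.omit)
  X <- model.matrix(tt, mf)
  eta <- drop(X %*% object$coefficients)
  if (type == "link") return(eta)
  p <- plogis(eta)
  if (type == "cure") return(p)
  if (is.null(times)) stop("`times` is required for type = \"survival\"")
  out <- vapply(times, function(ti) leg_survival(ti, p, object$lambda),
                numeric(length(p)))
  out <- matrix(out, nrow = length(p),
                dimnames = list(NULL, paste0("t=", times)))
  out
}

#' Model-based cure fractions
#'
#' Per-subject predicted cure probabilities and their cohort mean, the
#' model-based analogue of the cure fraction read off a Kaplan-Meier
#' plateau.
#'
#' @param object A converged `"legcure"` fit.
#' @param newdata Data frame of covariates (typically the fitting data).
#' @return A list with `per_subject` (probabilities in (0,1)), `mean`
#'   (their average) and `mean_percent` (the average as a percentage).
#' @export
cure_fraction <- function(object, newdata) {
  p <- predict(object, newdata, type = "cure")
  list(per_subject = p, mean = mean(p), mean_percent = 100 * mean(p))
}

#' @export
residuals.legcure <- function(object, newdata, type = c("cox-snell"), ...) {
  type <- match.arg(type)
  if (object$boundary) stop("boundary fit: residuals undefined")
  tt <- delete.response(object$terms)
  mf <- model.frame(object$terms, newdata, xlev = object$xlevels,
                    na.action = na.omit)
  y <- model.response(mf)
  X <- model.matrix(tt, mf)
  p <- plogis(drop(X %*% object$coefficients))
  -log(leg_survival(as.numeric(y[, "time"]), p, object$lambda))
}

#' Simulate outcomes from a fitted LEG cure model
#'
#' Draws new event times under the fitted parameters for the covariate rows
#' in `newdata`: latent cause count geometric in the predicted cure
#' probability, event time exponential with rate `M * lambda`, no censoring
#' applied (times for cured subjects are `Inf`).
#'
#' @param object A converged `"legcure"` fit.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed, handled as in [stats::simulate()].
#' @param newdata Covariate rows to simulate for.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of latent event times (days).
#' @export
simulate.legcure <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata, type = "cure")
  out <- replicate(nsim, {
    M <- rgeom(length(p), prob = p)
    ti <- rep(Inf, length(p))
    sus <- M > 0
    ti[sus] <- rexp(sum(sus), rate = M[sus] * object$lambda)
    ti
  })
  as.data.frame(matrix(out, nrow = length(p),
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' @export
plot.legcure <- function(x, newdata, times = NULL, col = "steelblue",
                         xlab = "Days since diagnosis",
                         ylab = "Population survival", ...) {
  if (is.null(times)) times <- seq(0, 3650, length.out = 200)
  S <- predict(x, newdata, type = "survival", times = times)
  plot(times, S[1, ], type = "l", ylim = c(0, 1), col = col,
       xlab = xlab, ylab = ylab, ...)
  if (nrow(S) > 1)
    for (i in 2:nrow(S)) lines(times, S[i, ], col = col)
  invisible(x)
}
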