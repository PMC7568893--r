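test_that("intercept-only fit recovers known generative parameters", {
  cfg <- cohort_config(n = 5000, formula = ~1,
                       beta = c("(Intercept)" = 0.579), lambda = 0.002)
  d <- generate_cohort(cfg, seed = 11)
  fit <- legcure(survival::Surv(time_days, event) ~ 1, data = d)
  expect_true(fit$converged)
  expect_equal(fit$n_events + fit$n_censored, 5000L)
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit)[["(Intercept)"]] - 0.579), 3 * se[["(Intercept)"]])
  expect_lt(abs(fit$log_lambda - log(0.002)), 3 * se[["log_lambda"]])
  ## covariance is symmetric with positive diagonal
  expect_equal(vcov(fit), t(vcov(fit)))
  expect_true(all(diag(vcov(fit)) > 0))
})

test_that("full-covariate fit recovers truth within 3 SE at n = 5000", {
  cfg <- cohort_config(n = 5000)
  d <- generate_cohort(cfg, seed = 3)
  fit <- legcure(full_formula, data = d, restarts = 1)
  expect_true(fit$converged)
  est <- c(coef(fit), log_lambda = fit$log_lambda)
  truth <- c(cfg$beta, log_lambda = log(cfg$lambda))
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(est - truth[names(est)]) < 3 * se))
})

test_that("the optimum is stable across jittered restarts", {
  d <- small_cohort(n = 427, seed = 5)
  fits <- lapply(1:3, function(s)
    legcure(full_formula, data = d, restarts = 4, restart_seed = s))
  base <- c(coef(fits[[1]]), fits[[1]]$log_lambda)
  for (f in fits[-1])
    expect_equal(c(coef(f), f$log_lambda), base, tolerance = 1e-4)
})

test_that("degenerate designs and event patterns are reported, not crashed", {
  d <- small_cohort(n = 60, seed = 8)
  ## zero events: boundary flag, p -> 1
  d0 <- d
  d0$event <- 0
  fit0 <- legcure(survival::Surv(time_days, event) ~ 1, data = d0)
  expect_false(fit0$converged)
  expect_true(fit0$boundary)
  expect_error(summary(fit0), "converge")
  ## rank-deficient design names the collinear column
  d$dup <- d$age_years
  expect_error(
    legcure(survival::Surv(time_days, event) ~ age_years + dup, data = d),
    "rank deficient.*dup")
})

test_that("fits on the no-cure ridge are flagged, interior fits are not", {
  ## for some study-sized realizations the likelihood is maximized in the
  ## lambda -> 0, p -> 0 limit (a heavy-tailed model with no cured
  ## subjects); such fits must carry the near_boundary diagnostic and
  ## still dominate the generative truth in likelihood
  cfg <- cohort_config()
  d7 <- generate_cohort(cfg, seed = 7)
  fit7 <- legcure(full_formula, data = d7)
  expect_true(fit7$near_boundary)
  X <- stats::model.matrix(cfg$formula, d7)
  expect_gte(fit7$loglik,
             leg_loglik(d7$time_days, d7$event, X, cfg$beta[colnames(X)],
                        log(cfg$lambda)))
  d1 <- generate_cohort(cfg, seed = 1)
  expect_false(legcure(full_formula, data = d1)$near_boundary)
})

test_that("Wald summary reproduces textbook odds-ratio arithmetic", {
  fit <- fake_fit(c("(Intercept)" = 0, x = 0), c(1, 1))
  tab <- summary(fit, level = 0.95)$table
  expect_equal(tab$odds_ratio, c(1, 1))
  expect_equal(tab$ci_low, rep(exp(-qnorm(0.975)), 2), tolerance = 1e-6)
  expect_equal(round(tab$ci_low[1], 2), 0.14)
  expect_equal(round(tab$ci_high[1], 2), 7.1)
  expect_equal(tab$p_value, c(1, 1))
  expect_false(any(tab$significant))
  expect_error(summary(fit, level = 1.5), "level")
  ## narrower level narrows the interval
  tab90 <- summary(fit, level = 0.90)$table
  expect_true(all(tab90$ci_high < tab$ci_high))
})

test_that("pairwise contrasts combine coefficients and covariance correctly", {
  pr <- published_rows()
  est <- setNames(c(-1.4, pr$estimate), c("(Intercept)", pr$term))
  fit <- fake_fit(est, c(1, pr$se))
  ## null contrast
  same <- pairwise_contrast(fit, "diagnosis", "HD", "HD")
  expect_equal(same$odds_ratio, 1)
  expect_equal(same$p_value, 1)
  ## HD vs NHL point estimate from the published coefficients
  hd_nhl <- pairwise_contrast(fit, "diagnosis", "HD", "NHL")
  expect_equal(hd_nhl$odds_ratio, exp(1.53 - 0.52), tolerance = 1e-12)
  expect_equal(round(hd_nhl$odds_ratio, 2), 2.75)
  ## a contrast against the reference level equals the coefficient itself
  hd_all <- pairwise_contrast(fit, "diagnosis", "HD", "ALL")
  expect_equal(hd_all$estimate, 1.53)
  expect_equal(hd_all$se, 0.53)
  expect_error(pairwise_contrast(fit, "diagnosis", "HD", "XX"),
               "valid levels")
  expect_error(pairwise_contrast(fit, "nope", "a", "b"), "unknown factor")
})

test_that("contrast inversion symmetry holds on a real fit", {
  d <- small_cohort(n = 427, seed = 12)
  fit <- legcure(full_formula, data = d, restarts = 1)
  ab <- pairwise_contrast(fit, "diagnosis", "HD", "NHL")
  ba <- pairwise_contrast(fit, "diagnosis", "NHL", "HD")
  expect_equal(ab$odds_ratio * ba$odds_ratio, 1, tolerance = 1e-12)
  expect_equal(ab$se, ba$se)
  expect_equal(ab$p_value, ba$p_value)
  ## covariance term matters: SE differs from the no-covariance formula
  k <- length(coef(fit))
  V <- vcov(fit)[seq_len(k), seq_len(k)]
  expect_equal(ab$se,
               sqrt(V["diagnosisHD", "diagnosisHD"] +
                      V["diagnosisNHL", "diagnosisNHL"] -
                      2 * V["diagnosisHD", "diagnosisNHL"]),
               tolerance = 1e-12)
})

test_that("predicted cure fractions behave as probabilities", {
  fit <- fake_fit(c("(Intercept)" = 0.579), 0.1)
  fit$terms <- terms(~1)
  fit$xlevels <- list()
  cf <- cure_fraction(fit, data.frame(x = numeric(10)))
  expect_equal(cf$mean_percent, 64.08373, tolerance = 1e-4)
  expect_equal(sd(cf$per_subject), 0)
  expect_true(all(cf$per_subject > 0 & cf$per_subject < 1))
})

test_that("cohort-mean cure prediction is unbiased for generative truth at n = 5000", {
  ## replicate-level Monte-Carlo check: the mean signed error of the
  ## model-based cure fraction across independent cohorts must be within
  ## 3 Monte-Carlo SEs of zero
  cfg <- cohort_config(n = 5000)
  errs <- vapply(1:10, function(s) {
    covs <- sample_covariates(cfg, seed = 20 + s)
    d <- sample_outcomes(covs, cfg, seed = 120 + s, latent = TRUE)
    fit <- legcure(full_formula, data = d, restarts = 1)
    cf <- cure_fraction(fit, d)
    expect_true(all(cf$per_subject > 0 & cf$per_subject < 1))
    cf$mean - mean(d$.p)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))
})

test_that("predict, simulate and residuals are coherent with the model", {
  d <- small_cohort(n = 427, seed = 31)
  fit <- legcure(full_formula, data = d, restarts = 1)
  p <- predict(fit, d, type = "cure")
  eta <- predict(fit, d, type = "link")
  expect_equal(p, plogis(eta))
  S <- predict(fit, d, type = "survival", times = c(0, 365, 3650))
  expect_equal(unname(S[, 1]), rep(1, nrow(d)))
  expect_true(all(diff(t(S)) <= 0))           # non-increasing in time
  expect_true(all(S[, 3] >= p))               # bounded below by cure prob
  ## Cox-Snell residuals are -log S at the observed times
  r <- residuals(fit, d)
  expect_equal(r, -log(leg_survival(d$time_days, p, fit$lambda)))
  ## simulate: cured subjects get infinite latent times
  sims <- simulate(fit, nsim = 2, seed = 1, newdata = d)
  expect_equal(dim(sims), c(nrow(d), 2L))
  expect_true(all(sims$sim_1 > 0))
  expect_gt(mean(is.infinite(sims$sim_1)), 0.3)
})
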