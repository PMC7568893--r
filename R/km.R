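#' Kaplan-Meier estimation with Greenwood variances
#'
#' Product-limit survival estimates, optionally stratified, computed through
#' [survival::survfit()] with deaths preceding censorings at tied times (the
#' standard risk-set convention).  Greenwood's variance
#' \eqn{\hat S(t)^2 \sum_{t_j \le t} d_j / (n_j (n_j - d_j))} is recomputed
#' from the extracted risk and event counts, and pointwise confidence
#' intervals use the complementary log-log transform, clipped to [0, 1].
#'
#' @param times Follow-up times in days (non-negative).
#' @param events Event indicators (1 = event, 0 = censored).
#' @param strata Optional vector of stratum labels, one per record.
#' @param conf.level Confidence level for pointwise intervals.
#' @return An object of class `"leg_km"`: a list with one element per
#'   stratum, each a data frame with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `std_err` (Greenwood SE of the survival
#'   probability), `ci_low`, `ci_high`, plus attributes recording the
#'   stratum sizes and last follow-up per stratum.
#' @examples
#' km <- km_fit(c(2, 3, 5), c(1, 0, 1))
#' survival_at(km, 4)      # step-function value 2/3
#' @export
km_fit <- function(times, events, strata = NULL, conf.level = 0.95) {
  if (any(times < 0)) stop("times must be non-negative")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  if (is.null(strata)) strata <- rep("all", length(times))
  if (length(strata) != length(times))
    stop("strata labels must align with records")
  strata <- as.character(strata)
  lv <- unique(strata)
  curves <- list()
  maxfu <- numeric(0)
  for (s in lv) {
    idx <- strata == s
    if (!any(idx)) stop("empty stratum: ", s)
    sf <- survival::survfit(
      survival::Surv(times[idx], events[idx]) ~ 1,
      conf.type = "log-log", conf.int = conf.level)
    d <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    survival = sf$surv)
    ## Greenwood variance from the counts themselves
    term <- ifelse(d$n_event > 0,
                   d$n_event / (d$n_risk * (d$n_risk - d$n_event)), 0)
    term[d$n_event > 0 & d$n_event == d$n_risk] <- Inf   # S drops to 0
    gw <- cumsum(term)
    d$std_err <- ifelse(d$survival > 0, d$survival * sqrt(gw), 0)
    d$ci_low <- pmin(pmax(ifelse(is.na(sf$lower), d$survival, sf$lower), 0), 1)
    d$ci_high <- pmin(pmax(ifelse(is.na(sf$upper), d$survival, sf$upper), 0), 1)
    d$stratum <- s
    curves[[s]] <- d
    maxfu[s] <- max(times[idx])
  }
  structure(curves, class = "leg_km", conf.level = conf.level,
            max_followup = maxfu,
            n = vapply(lv, function(s) sum(strata == s), integer(1)))
}

#' @export
print.leg_km <- function(x, ...) {
  cat("Kaplan-Meier estimate (", length(x), " stratum/strata)\n", sep = "")
  for (s in names(x)) {
    d <- x[[s]]
    cat(sprintf("  %s: n = %d, events = %d, final S = %.3f\n",
                s, attr(x, "n")[s], sum(d$n_event),
                if (nrow(d)) d$survival[nrow(d)] else 1))
  }
  invisible(x)
}

#' @export
as.data.frame.leg_km <- function(x, ...) {
  do.call(rbind, c(unname(x), list(make.row.names = FALSE)))
}

#' Survival probabilities at fixed horizons
#'
#' Right-continuous step-function evaluation of a Kaplan-Meier curve at the
#' requested horizons, with Greenwood confidence limits carried along.
#' Horizons past the last observed follow-up return the final value with
#' `beyond_data = TRUE`.
#'
#' @param curve A `"leg_km"` object from [km_fit()].
#' @param horizons Times in days (non-negative).
#' @param stratum Which stratum to evaluate (default the first).
#' @return A data frame: `horizon`, `survival`, `std_err`, `ci_low`,
#'   `ci_high`, `beyond_data`.
#' @export
survival_at <- function(curve, horizons, stratum = names(curve)[1]) {
  if (any(horizons < 0)) stop("horizons must be non-negative")
  d <- curve[[stratum]]
  if (is.null(d)) stop("unknown stratum: ", stratum)
  maxfu <- attr(curve, "max_followup")[stratum]
  out <- lapply(horizons, function(h) {
    i <- findInterval(h, d$time)          # last event/censor time <= h
    if (i == 0)
      data.frame(horizon = h, survival = 1, std_err = 0,
                 ci_low = 1, ci_high = 1, beyond_data = FALSE)
    else
      data.frame(horizon = h, survival = d$survival[i], std_err = d$std_err[i],
                 ci_low = d$ci_low[i], ci_high = d$ci_high[i],
                 beyond_data = h > maxfu)
  })
  do.call(rbind, out)
}

#' Plateau-based cure fraction from a Kaplan-Meier curve
#'
#' Reads the cure fraction off the curve's plateau, formalized as the
#' Kaplan-Meier estimate at the largest observed event time.  The
#' `credible` flag records whether censored follow-up extends beyond that
#' time: without it, the plateau may simply reflect exhausted follow-up
#' rather than cured subjects.
#'
#' @param curve A `"leg_km"` object.
#' @param stratum Which stratum to use (default the first).
#' @return A list: `cure_fraction`, `plateau_onset` (days, the last event
#'   time), `credible` (any censoring after the last event).
#' @export
plateau_cure_fraction <- function(curve, stratum = names(curve)[1]) {
  d <- curve[[stratum]]
  if (is.null(d)) stop("unknown stratum: ", stratum)
  ev <- d$n_event > 0
  if (!any(ev)) stop("no events in stratum '", stratum, "': no plateau definable")
  last_event <- max(d$time[ev])
  i <- max(which(d$time == last_event & ev))
  list(cure_fraction = d$survival[d$time == last_event & ev][1],
       plateau_onset = last_event,
       credible = attr(curve, "max_followup")[[stratum]] > last_event)
}

#' @export
plot.leg_km <- function(x, col = NULL, xlab = "Days since diagnosis",
                        ylab = "Survival probability", conf = TRUE, ...) {
  if (is.null(col)) col <- seq_along(x)
  plot(NA, xlim = c(0, max(attr(x, "max_followup"))), ylim = c(0, 1),
       xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(x)) {
    d <- x[[i]]
    tt <- c(0, rep(d$time, each = 2))
    ss <- c(1, 1, rep(d$survival, each = 2)[-(2 * nrow(d))])
    lines(tt, ss, col = col[i])
    if (conf && nrow(d)) {
      lines(d$time, d$ci_low, col = col[i], lty = 3, type = "s")
      lines(d$time, d$ci_high, col = col[i], lty = 3, type = "s")
    }
  }
  if (length(x) > 1) legend("bottomleft", legend = names(x), col = col, lty = 1)
  invisible(x)
}
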