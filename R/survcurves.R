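#' Kaplan-Meier product-limit estimate
#'
#' Wraps `survival::survfit` for one group and extracts the curve at
#' event times only.  Censorings tied with events are handled with the
#' standard convention: events precede censorings, so a subject censored
#' at t is still at risk for events at t.
#'
#' @param time positive follow-up times in days.
#' @param event logical event indicator.
#' @return Object of class `ppsn_km`: `event_times`, `survival`,
#'   `at_risk` (count just before each event time), `n`, `n_censored`,
#'   and `fit` (the underlying `survfit`).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event))
  keep <- !is.na(time) & !is.na(event)
  time <- time[keep]; event <- as.logical(event[keep])
  if (length(time) == 0L) stop("empty survival data")
  if (any(time <= 0)) stop("times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  has_event <- fit$n.event > 0
  structure(
    list(event_times = fit$time[has_event],
         survival = fit$surv[has_event],
         at_risk = fit$n.risk[has_event],
         n = length(time), n_censored = sum(!event), fit = fit),
    class = "ppsn_km")
}

#' @export
print.ppsn_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, censored = %d\n",
              x$n, x$n - x$n_censored, x$n_censored))
  if (length(x$event_times) > 0) {
    print(utils::head(data.frame(time = x$event_times, survival = x$survival,
                                 at_risk = x$at_risk), 10))
  }
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard unweighted log-rank via `survival::survdiff`: chi-square
#' statistic on 1 degree of freedom for two groups, with per-group
#' observed and expected event counts.
#'
#' @param time positive follow-up times.
#' @param event logical event indicator.
#' @param group two-level grouping vector.
#' @return List of class `ppsn_logrank`: `chi2`, `df`, `p`, `observed`,
#'   `expected` (named by group).
#' @export
log_rank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- as.logical(event[keep])
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) < 2L) stop("log-rank requires two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  structure(
    list(chi2 = sd$chisq, df = df,
         p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
         observed = stats::setNames(sd$obs, levels(group)),
         expected = stats::setNames(sd$exp, levels(group))),
    class = "ppsn_logrank")
}

#' @export
print.ppsn_logrank <- function(x, ...) {
  cat(sprintf("Log-rank: chi2 = %.3f on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Restrict survival data to a horizon
#'
#' Administratively censors at the horizon: any subject followed beyond
#' it is cut back to the horizon and events after the horizon become
#' non-events.  Idempotent; composing two restrictions is equivalent to
#' restricting at the smaller horizon.  `horizon = Inf` is the identity.
#'
#' @param time follow-up times in days.
#' @param event logical event indicator.
#' @param horizon horizon in days (> 0); see [horizon_days()].
#' @return List: `time`, `event` after restriction.
#' @export
restrict_horizon <- function(time, event, horizon) {
  stopifnot(horizon > 0, length(time) == length(event))
  over <- !is.na(time) & time > horizon
  event <- as.logical(event)
  event[over] <- FALSE
  time[over] <- horizon
  list(time = time, event = event)
}

#' Horizon day counts
#'
#' 3-year = 1095 days, 5-year = 1825 days, total = Inf.
#'
#' @param label `"3y"`, `"5y"` or `"total"`.
#' @return Horizon in days.
#' @export
horizon_days <- function(label = c("3y", "5y", "total")) {
  label <- match.arg(label)
  switch(label, "3y" = 1095, "5y" = 1825, "total" = Inf)
}

#' Binary event status at a horizon
#'
#' Converts survival data to a horizon-restricted binary endpoint for
#' logistic analyses: an event within the horizon is positive, follow-up
#' beyond the horizon without an event is negative, and a subject
#' censored event-free before the horizon cannot be classified and is
#' excluded (returned as missing, with the exclusion count).
#'
#' @param time follow-up times in days.
#' @param event logical event indicator.
#' @param horizon horizon in days (> 0).
#' @return List: `outcome` (logical with NA for exclusions),
#'   `n_excluded`.
#' @export
horizon_binary_outcome <- function(time, event, horizon) {
  stopifnot(horizon > 0, length(time) == length(event))
  event <- as.logical(event)
  if (is.infinite(horizon)) {
    # unrestricted endpoint: the raw event indicator, no exclusions
    if (all(is.na(event))) stop("all subjects excluded at this horizon")
    return(list(outcome = event, n_excluded = 0L))
  }
  out <- rep(NA, length(time))
  out[event & time <= horizon] <- TRUE
  out[time >= horizon & !(event & time <= horizon)] <- FALSE
  n_excluded <- sum(is.na(out) & !is.na(time) & !is.na(event))
  if (all(is.na(out))) stop("all subjects excluded at this horizon")
  list(outcome = out, n_excluded = n_excluded)
}

#' Export a set of KM curves as a tall table
#'
#' @param curves named list of `ppsn_km` objects (names become the
#'   `group` column).
#' @return Data frame: `group`, `time`, `survival`, `at_risk`.
#' @export
km_table <- function(curves) {
  do.call(rbind, lapply(names(curves), function(g) {
    k <- curves[[g]]
    if (length(k$event_times) == 0L) {
      return(data.frame(group = character(0), time = numeric(0),
                        survival = numeric(0), at_risk = numeric(0)))
    }
    data.frame(group = g, time = k$event_times, survival = k$survival,
               at_risk = k$at_risk, stringsAsFactors = FALSE)
  }))
}
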