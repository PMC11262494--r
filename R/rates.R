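PY_SCALE <- 1e4
Z95 <- stats::qnorm(0.975)

#' Exposure-adjusted incidence summary for one endpoint and arm
#'
#' Counts first events and accumulates patient-years at risk for one
#' endpoint: each patient contributes `min(first event, censoring)` days
#' of exposure (converted at 365.25 days/year) and one event if the event
#' came first. The rate is `events / patient_years`, scaled per 10 000
#' patient-years.
#'
#' @param fev First-event table from [first_events()].
#' @param endpoint Endpoint name.
#' @param arms Arm labels to summarize (default both arms present).
#' @return A data frame with one row per arm: `endpoint`, `arm`, `events`,
#'   `patient_years`, `rate`.
#' @export
summarize_endpoint <- function(fev, endpoint, arms = NULL) {
  patients <- attr(fev, "patients")
  if (is.null(arms)) arms <- unique(patients$arm)
  rows <- lapply(arms, function(a) {
    exp <- endpoint_exposure(fev, endpoint, arm = a)
    py <- sum(exp$time_days) / DAYS_PER_YEAR
    if (py <= 0) stop("zero patient-years for endpoint ", endpoint,
                      " in arm ", a)
    d <- sum(exp$event)
    data.frame(endpoint = endpoint, arm = a, events = d,
               patient_years = py, rate = PY_SCALE * d / py,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Between-arm incidence-rate difference with a Wald 95% CI
#'
#' The difference of two exposure-adjusted incidence rates (active minus
#' control, per 10 000 patient-years) with a normal-approximation (Wald)
#' interval using the Poisson variance of each rate,
#' `se = 10000 * sqrt(d_a / PY_a^2 + d_c / PY_c^2)`.
#'
#' @param summary_active,summary_control One-row summaries from
#'   [summarize_endpoint()] for the same endpoint.
#' @return One-row data frame: `endpoint`, `rate_active`, `rate_control`,
#'   `delta`, `se`, `ci_lo`, `ci_hi`, and the per-arm `events_*`,
#'   `patient_years_*` carried along for rate resampling.
#' @export
rate_difference <- function(summary_active, summary_control) {
  stopifnot(summary_active$endpoint == summary_control$endpoint,
            summary_active$patient_years > 0,
            summary_control$patient_years > 0)
  delta <- summary_active$rate - summary_control$rate
  se <- PY_SCALE * sqrt(
    summary_active$events / summary_active$patient_years^2 +
      summary_control$events / summary_control$patient_years^2)
  data.frame(endpoint = summary_active$endpoint,
             rate_active = summary_active$rate,
             rate_control = summary_control$rate,
             delta = delta, se = se,
             ci_lo = delta - Z95 * se, ci_hi = delta + Z95 * se,
             events_active = summary_active$events,
             patient_years_active = summary_active$patient_years,
             events_control = summary_control$events,
             patient_years_control = summary_control$patient_years,
             stringsAsFactors = FALSE)
}

#' Rate-difference table for every endpoint of an MCDA model
#'
#' Convenience wrapper running [summarize_endpoint()] and
#' [rate_difference()] over a model's endpoints.
#'
#' @param fev First-event table from [first_events()].
#' @param tree A `br_value_tree`.
#' @param model MCDA model, 1 or 2.
#' @param active,control Arm labels.
#' @return A data frame with one [rate_difference()] row per endpoint.
#' @export
rate_table <- function(fev, tree, model = 1,
                       active = "active", control = "control") {
  eps <- model_endpoints(tree, model)
  rows <- lapply(eps, function(e) {
    s <- summarize_endpoint(fev, e, arms = c(active, control))
    rate_difference(s[s$arm == active, ], s[s$arm == control, ])
  })
  do.call(rbind, rows)
}

#' Rate-difference table from printed aggregate summaries
#'
#' Builds the same table as [rate_table()] from pre-aggregated inputs —
#' per-endpoint printed rates and 95% CIs of the rate difference, as
#' published tables report them. The standard error is recovered from the
#' CI width as `(ci_hi - ci_lo) / 3.92`.
#'
#' @param x Data frame with columns `endpoint`, `ci_lo`, `ci_hi` and
#'   either `delta` or both `rate_active` and `rate_control`.
#' @return A data frame with columns `endpoint`, `rate_active`,
#'   `rate_control`, `delta`, `se`, `ci_lo`, `ci_hi`.
#' @export
aggregate_rate_table <- function(x) {
  stopifnot(all(c("endpoint", "ci_lo", "ci_hi") %in% names(x)))
  if (is.null(x$delta)) x$delta <- x$rate_active - x$rate_control
  if (is.null(x$rate_active)) x$rate_active <- NA_real_
  if (is.null(x$rate_control)) x$rate_control <- NA_real_
  data.frame(endpoint = x$endpoint, rate_active = x$rate_active,
             rate_control = x$rate_control, delta = x$delta,
             se = (x$ci_hi - x$ci_lo) / (2 * Z95),
             ci_lo = x$ci_lo, ci_hi = x$ci_hi, stringsAsFactors = FALSE)
}

#' Number needed to treat or harm
#'
#' The number of patient-years of treatment per one event prevented
#' (`delta < 0`, NNT) or caused (`delta > 0`, NNH): `10000 / |delta|` on
#' the per-10 000-patient-years scale. A zero difference is flagged
#' undefined (infinite), not an error. If endpoint roles are supplied, a
#' benefit endpoint whose excess runs against treatment (or vice versa) is
#' flagged `discordant`, so NNH-style excesses on benefit endpoints are
#' visible.
#'
#' @param rd Rate-difference table ([rate_difference()] rows).
#' @param roles Optional named character vector (`"benefit"`/`"risk"`) or
#'   a `br_value_tree`.
#' @return Data frame `endpoint`, `delta`, `nn` (patient-years per event),
#'   `type` (`"NNT"`/`"NNH"`/`"undefined"`), `discordant`.
#' @export
nnt <- function(rd, roles = NULL) {
  if (inherits(roles, "br_value_tree"))
    roles <- setNames(roles$role, roles$endpoint)
  nn <- ifelse(rd$delta == 0, Inf, PY_SCALE / abs(rd$delta))
  type <- ifelse(rd$delta == 0, "undefined",
                 ifelse(rd$delta < 0, "NNT", "NNH"))
  disc <- rep(NA, nrow(rd))
  if (!is.null(roles)) {
    role <- roles[rd$endpoint]
    disc <- (role == "benefit" & rd$delta > 0) |
      (role == "risk" & rd$delta < 0)
    disc[rd$delta == 0] <- FALSE
  }
  data.frame(endpoint = rd$endpoint, delta = rd$delta, nn = nn,
             type = type, discordant = disc, stringsAsFactors = FALSE)
}

#' Kaplan-Meier cumulative incidence for one endpoint and arm
#'
#' Product-limit estimate of the cumulative incidence (1 - survival) with
#' Greenwood standard errors, via [survival::survfit()]. Ties at the same
#' event day are handled with the standard simultaneous-death convention.
#'
#' @param fev First-event table from [first_events()].
#' @param endpoint Endpoint name.
#' @param arm Arm label.
#' @return A list of class `km_curve`: `times` (days), `cuminc`, `se`
#'   (Greenwood), `at_risk`, `n`, and the per-patient `data` used.
#' @export
km_curve <- function(fev, endpoint, arm) {
  exp <- endpoint_exposure(fev, endpoint, arm = arm)
  if (nrow(exp) == 0L) stop("empty cohort for arm ", arm)
  fit <- survival::survfit(
    survival::Surv(time_days, event) ~ 1, data = exp, conf.type = "none")
  structure(list(times = fit$time, cuminc = 1 - fit$surv,
                 se = fit$std.err * fit$surv,  # std.err is on log scale
                 at_risk = fit$n.risk, n = fit$n, endpoint = endpoint,
                 arm = arm, data = exp),
            class = "km_curve")
}

km_step <- function(curve, what = c("cuminc", "se")) {
  what <- match.arg(what)
  y <- curve[[what]]
  if (length(curve$times) == 0L)
    return(function(t) rep(0, length(t)))
  stats::stepfun(curve$times, c(0, y), right = FALSE)
}

at_risk_fraction <- function(curve, t) {
  vapply(t, function(tt) mean(curve$data$time_days >= tt), numeric(1))
}

#' Between-arm Kaplan-Meier cumulative-incidence difference
#'
#' Difference of the two arms' cumulative incidences on the merged event
#' grid, restricted (after Pocock's suggestion) to the period in which at
#' least `at_risk_floor` of each arm's patients remain at risk; the curve
#' is truncated at the last grid time where both arms still meet the
#' floor. `at_risk_floor = 0` disables the restriction.
#'
#' @param curve_active,curve_control `km_curve` objects from the same
#'   scope.
#' @param at_risk_floor Minimum at-risk fraction (default 0.10).
#' @return Data frame `time_days`, `cuminc_active`, `cuminc_control`,
#'   `diff`, with the truncation time in attribute `"truncated_at"`.
#' @export
km_difference_curve <- function(curve_active, curve_control,
                                at_risk_floor = 0.10) {
  grid <- sort(unique(c(0, curve_active$times, curve_control$times)))
  fa <- km_step(curve_active)
  fc <- km_step(curve_control)
  keep <- at_risk_fraction(curve_active, grid) >= at_risk_floor &
    at_risk_fraction(curve_control, grid) >= at_risk_floor
  if (at_risk_floor > 0 && !all(keep)) {
    t_max <- if (any(keep)) max(grid[keep]) else 0
    grid <- grid[grid <= t_max]
  } else t_max <- max(grid)
  out <- data.frame(time_days = grid, cuminc_active = fa(grid),
                    cuminc_control = fc(grid))
  out$diff <- out$cuminc_active - out$cuminc_control
  attr(out, "truncated_at") <- t_max
  out
}
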