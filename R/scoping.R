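#' Define an analysis data scope
#'
#' Two scopes mirror the usual populations of an event-driven trial:
#' * `"itt"` — intention-to-treat: all randomized patients, events counted
#'   from randomization to the administrative (efficacy cutoff) censoring
#'   time, regardless of treatment discontinuation.
#' * `"on_treatment"` — treated patients only, events counted until the
#'   last study-drug dose plus a short washout window (default 2 days);
#'   later events and follow-up are excluded.
#'
#' @param name `"itt"` or `"on_treatment"`.
#' @param window_after_last_dose_days Washout window in days (>= 0);
#'   ignored for ITT.
#' @return A list of class `scope_config`.
#' @export
scope_config <- function(name = c("itt", "on_treatment"),
                         window_after_last_dose_days = 2L) {
  name <- match.arg(name)
  stopifnot(window_after_last_dose_days >= 0)
  structure(list(name = name,
                 window_after_last_dose_days =
                   as.numeric(window_after_last_dose_days)),
            class = "scope_config")
}

#' Apply an analysis scope to trial data
#'
#' Computes each patient's censoring time under the scope and drops events
#' beyond it. Under ITT the censoring time is the administrative follow-up
#' end and all events are kept. On-treatment, the censoring time is
#' `min(followup_end, last_dose + window)` — an event exactly at
#' `last_dose + window` is still included (closed interval) — and patients
#' who never received study drug (`last_dose_days` missing) leave the
#' population entirely.
#'
#' @param trial A `br_trial`, or a list with `patients` and `events` data
#'   frames in the documented layout.
#' @param scope A [scope_config()].
#' @param group Optional logical/character filter: a vector of patient ids
#'   to keep (subgroup support), applied before scoping.
#' @return A list of class `br_scoped` with `patients` (including a
#'   `censor_days` column), `events` (scoped), and `scope`.
#' @export
apply_scope <- function(trial, scope = scope_config("itt"), group = NULL) {
  stopifnot(inherits(scope, "scope_config"))
  patients <- trial$patients
  events <- trial$events
  if (!is.null(group)) {
    patients <- patients[patients$patient_id %in% group, , drop = FALSE]
  }
  if (!all(events$patient_id %in% trial$patients$patient_id))
    stop("event references unknown patient_id")
  if (scope$name == "itt") {
    patients$censor_days <- patients$followup_end_days
  } else {
    dosed <- !is.na(patients$last_dose_days)
    patients <- patients[dosed, , drop = FALSE]
    patients$censor_days <- pmin(
      patients$followup_end_days,
      patients$last_dose_days + scope$window_after_last_dose_days)
  }
  events <- events[events$patient_id %in% patients$patient_id, , drop = FALSE]
  cens <- patients$censor_days[match(events$patient_id, patients$patient_id)]
  events <- events[events$time_days <= cens, , drop = FALSE]
  structure(list(patients = patients, events = events, scope = scope),
            class = "br_scoped")
}

#' First qualifying event per patient and endpoint
#'
#' Reduces scoped events to at most one record per (patient, endpoint):
#' the earliest occurrence. Fatal occurrences are attributed only to the
#' fatal endpoint of the value tree — never to a nonfatal endpoint — so
#' deaths are not double-counted; nonfatal endpoints of the same patient
#' keep their own (marginal) first events.
#'
#' @param scoped A `br_scoped` from [apply_scope()].
#' @param tree A `br_value_tree`; events naming an endpoint outside the
#'   tree raise an error.
#' @return A data frame `patient_id`, `endpoint`, `time_days`, `fatal` with
#'   at most one row per patient x endpoint, plus the scoped `patients`
#'   carried in attribute `"patients"`.
#' @export
first_events <- function(scoped, tree) {
  stopifnot(inherits(scoped, "br_scoped"))
  ev <- scoped$events
  unknown <- setdiff(unique(ev$endpoint), tree$endpoint)
  if (length(unknown))
    stop("events name endpoints absent from the value tree: ",
         paste(unknown, collapse = ", "))
  fatal_eps <- tree$endpoint[tree$fatal]
  bad <- ev$fatal & !(ev$endpoint %in% fatal_eps)
  if (any(bad))
    stop("fatal occurrence attributed to a nonfatal endpoint: ",
         paste(unique(ev$endpoint[bad]), collapse = ", "))
  if (nrow(ev)) {
    o <- order(ev$patient_id, ev$endpoint, ev$time_days)
    ev <- ev[o, , drop = FALSE]
    ev <- ev[!duplicated(ev[c("patient_id", "endpoint")]), , drop = FALSE]
    rownames(ev) <- NULL
  }
  attr(ev, "patients") <- scoped$patients
  ev
}

#' Per-patient time at risk and event indicator for one endpoint
#'
#' Internal helper shared by the rate and Kaplan-Meier layers: for a given
#' endpoint, each patient contributes `min(first event time, censor time)`
#' of follow-up and an indicator of whether the event came first. Death
#' (the fatal endpoint's event) already truncates `censor_days` at data
#' generation / scoping, so no extra competing-risk handling happens here.
#'
#' @noRd
endpoint_exposure <- function(fev, endpoint, arm = NULL) {
  patients <- attr(fev, "patients")
  if (is.null(patients)) stop("first_events() output required")
  if (!is.null(arm)) patients <- patients[patients$arm == arm, , drop = FALSE]
  sel <- fev$endpoint == endpoint & fev$patient_id %in% patients$patient_id
  t_ev <- rep(NA_real_, nrow(patients))
  idx <- match(fev$patient_id[sel], patients$patient_id)
  t_ev[idx] <- fev$time_days[sel]
  time <- pmin(t_ev, patients$censor_days, na.rm = TRUE)
  status <- !is.na(t_ev) & t_ev <= patients$censor_days
  data.frame(patient_id = patients$patient_id, time_days = time,
             event = status, stringsAsFactors = FALSE)
}
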