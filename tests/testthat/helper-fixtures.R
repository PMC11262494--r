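# Hand-built five-patient trial used for scoping/first-event enumeration.
# Patient 1: two nonfatal MIs (day 30, 90), discontinued day 50.
# Patient 2: fatal event day 40 (routed to the fatal composite).
# Patient 3: nonfatal stroke day 20, then fatal composite day 60.
# Patient 4: event exactly at last dose + 2 (day 52, last dose 50).
# Patient 5: never dosed, event day 10.
tiny_trial <- function() {
  patients <- data.frame(
    patient_id = 1:5,
    arm = c("active", "active", "active", "control", "control"),
    followup_end_days = c(365, 40, 60, 365, 365),
    last_dose_days = c(50, 40, 60, 50, NA),
    stringsAsFactors = FALSE)
  events <- data.frame(
    patient_id = c(1L, 1L, 2L, 3L, 3L, 4L, 5L),
    endpoint = c("nonfatal_mi", "nonfatal_mi", "fatal_composite",
                 "nonfatal_stroke", "fatal_composite", "nonfatal_mi",
                 "nonfatal_mi"),
    time_days = c(30, 90, 40, 20, 60, 52, 10),
    fatal = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  structure(list(patients = patients, events = events, config = NULL),
            class = "br_trial")
}

tiny_tree <- function() {
  value_tree(
    endpoint_spec("fatal_composite", "risk", fatal = TRUE),
    endpoint_spec("nonfatal_mi", "benefit"),
    endpoint_spec("nonfatal_stroke", "benefit"))
}

# One default-condition synthetic trial, simulated once per test run.
default_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_trial(voyager_sim_config(seed = 11))
    cache
  }
})

# Independent product-limit estimator by direct enumeration (the KM oracle:
# a literal loop over distinct event times, no survival-package code).
naive_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ts, cuminc = 1 - surv)
}
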