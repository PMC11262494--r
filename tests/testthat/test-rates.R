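make_summary <- function(endpoint, arm, events, py) {
  data.frame(endpoint = endpoint, arm = arm, events = events,
             patient_years = py, rate = 1e4 * events / py,
             stringsAsFactors = FALSE)
}

test_that("incidence summaries are events over exposure, per 10 000 PY", {
  tr <- tiny_trial()
  tree <- tiny_tree()
  fev <- first_events(apply_scope(tr, scope_config("itt")), tree)
  s <- summarize_endpoint(fev, "nonfatal_mi", arms = "control")
  # control arm: patient 4 (event day 52 of 365 fu) + patient 5 (day 10)
  expect_identical(s$events, 2L)
  expect_equal(s$patient_years, (52 + 10) / 365.25)
  expect_equal(s$rate, 1e4 * 2 / s$patient_years)
  # endpoint with no events: zero rate, full follow-up exposure
  s0 <- summarize_endpoint(fev, "nonfatal_stroke", arms = "control")
  expect_identical(s0$events, 0L)
  expect_equal(s0$rate, 0)
  expect_equal(s0$patient_years, (365 + 365) / 365.25)
})

test_that("rate differences use the Poisson-variance Wald interval", {
  rd <- rate_difference(make_summary("e", "active", 2, 4),
                        make_summary("e", "control", 2, 4))
  expect_equal(rd$rate_active, 5000)
  expect_equal(rd$delta, 0)
  expect_equal(rd$ci_lo, -rd$ci_hi)
  rd2 <- rate_difference(make_summary("e", "active", 50, 1000),
                         make_summary("e", "control", 30, 1000))
  expect_equal(rd2$delta, 200)
  expect_equal(rd2$se, 1e4 * sqrt(50 / 1000^2 + 30 / 1000^2))
  expect_equal(rd2$ci_hi - rd2$ci_lo, 2 * qnorm(0.975) * rd2$se)
})

test_that("the Wald CI agrees with a parametric-bootstrap oracle", {
  rd <- rate_difference(make_summary("e", "active", 50, 1000),
                        make_summary("e", "control", 30, 1000))
  set.seed(123)
  boot <- 1e4 * (rpois(1e5, 50) - rpois(1e5, 30)) / 1000
  q <- unname(quantile(boot, c(0.025, 0.975)))
  width <- rd$ci_hi - rd$ci_lo
  expect_lt(abs(q[1] - rd$ci_lo), 0.02 * width)
  expect_lt(abs(q[2] - rd$ci_hi), 0.02 * width)
})

test_that("rates are invariant to consistent time-unit accounting", {
  tr <- tiny_trial()
  fev <- first_events(apply_scope(tr, scope_config("itt")), tiny_tree())
  s <- summarize_endpoint(fev, "nonfatal_mi", arms = "active")
  # recompute with exposure in days and the scale adjusted accordingly
  rate_days <- 1e4 * s$events / (s$patient_years * 365.25) * 365.25
  expect_equal(rate_days, s$rate)
})

test_that("NNT/NNH bookkeeping follows the sign of the excess", {
  rd <- data.frame(endpoint = c("a", "b", "c"),
                   delta = c(-120, -10000, 0))
  nn <- nnt(rd)
  expect_equal(nn$nn, c(1e4 / 120, 1, Inf))
  expect_identical(nn$type, c("NNT", "NNT", "undefined"))
  roles <- c(a = "benefit", b = "risk", c = "benefit")
  nn2 <- nnt(data.frame(endpoint = "a", delta = 40), c(a = "benefit"))
  expect_identical(nn2$type, "NNH")
  expect_true(nn2$discordant)
})

test_that("KM with no censoring equals the empirical CDF", {
  set.seed(4)
  n <- 60
  patients <- data.frame(patient_id = 1:n, arm = "active",
                         followup_end_days = 1e6, last_dose_days = 0)
  events <- data.frame(patient_id = 1:n, endpoint = "e",
                       time_days = rexp(n, 1 / 200), fatal = FALSE)
  tr <- structure(list(patients = patients, events = events), class = "br_trial")
  tree <- value_tree(endpoint_spec("e", "benefit", fatal = TRUE))
  fev <- first_events(apply_scope(tr, scope_config("itt")), tree)
  km <- km_curve(fev, "e", "active")
  expect_equal(km$cuminc, ecdf(events$time_days)(km$times),
               tolerance = 1e-10)
})

test_that("KM matches an independent product-limit enumeration", {
  set.seed(7)
  n <- 100
  t_ev <- rexp(n, 1 / 300)
  cens <- runif(n, 100, 900)
  patients <- data.frame(patient_id = 1:n, arm = "control",
                         followup_end_days = cens, last_dose_days = 0)
  keep <- t_ev <= cens
  events <- data.frame(patient_id = (1:n)[keep], endpoint = "e",
                       time_days = t_ev[keep], fatal = FALSE)
  tr <- structure(list(patients = patients, events = events), class = "br_trial")
  tree <- value_tree(endpoint_spec("e", "benefit", fatal = TRUE))
  fev <- first_events(apply_scope(tr, scope_config("itt")), tree)
  km <- km_curve(fev, "e", "control")
  oracle <- naive_km(pmin(t_ev, cens), keep)
  step <- stepfun(km$times, c(0, km$cuminc), right = FALSE)
  expect_equal(step(oracle$time), oracle$cuminc, tolerance = 1e-10)
  # all censored: cumulative incidence identically zero
  tr0 <- tr
  tr0$events <- events[0, ]
  fev0 <- first_events(apply_scope(tr0, scope_config("itt")), tree)
  km0 <- km_curve(fev0, "e", "control")
  expect_true(all(km0$cuminc == 0))
})

test_that("KM difference curves start at zero and honour the at-risk floor", {
  set.seed(12)
  n <- 80
  mk <- function(arm, rate) {
    t_ev <- rexp(n, rate)
    cens <- rep(400, n)
    keep <- t_ev <= cens
    list(patients = data.frame(patient_id = 1:n, arm = arm,
                               followup_end_days = cens, last_dose_days = 0),
         events = data.frame(patient_id = (1:n)[keep], endpoint = "e",
                             time_days = t_ev[keep], fatal = FALSE))
  }
  a <- mk("active", 1 / 150)
  b <- mk("control", 1 / 150)
  b$patients$patient_id <- b$patients$patient_id + n
  b$events$patient_id <- b$events$patient_id + n
  tr <- structure(list(patients = rbind(a$patients, b$patients),
                       events = rbind(a$events, b$events)),
                  class = "br_trial")
  tree <- value_tree(endpoint_spec("e", "benefit", fatal = TRUE))
  fev <- first_events(apply_scope(tr, scope_config("itt")), tree)
  ka <- km_curve(fev, "e", "active")
  kc <- km_curve(fev, "e", "control")
  dc <- km_difference_curve(ka, kc, at_risk_floor = 0)
  expect_equal(dc$diff[dc$time_days == 0], 0)
  expect_equal(max(dc$time_days), max(c(ka$times, kc$times)))
  # identical cohorts: difference identically zero
  d0 <- km_difference_curve(ka, ka, at_risk_floor = 0)
  expect_true(all(d0$diff == 0))
  # floor: truncation at the hand-computed last time both arms keep >= 10%
  dc10 <- km_difference_curve(ka, kc, at_risk_floor = 0.10)
  grid <- sort(unique(c(0, ka$times, kc$times)))
  frac <- function(cur, t) mean(cur$data$time_days >= t)
  ok <- sapply(grid, function(t) frac(ka, t) >= 0.1 && frac(kc, t) >= 0.1)
  expect_equal(attr(dc10, "truncated_at"), max(grid[ok]))
  expect_lte(max(dc10$time_days), max(grid[ok]))
})
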