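test_that("tornado bars are linear, symmetric, and exclude the fatal endpoint", {
  rd <- aggregate_rate_table(voyager_table1())
  w <- voyager_weights(utility_sd_nonfatal = 0.08)
  s <- one_way_sensitivity(rd, w, model = 1, tree = voyager_value_tree())
  expect_false("fatal_composite" %in% s$endpoint)
  expect_identical(nrow(s), 6L)
  for (i in seq_len(nrow(s))) {
    dr <- rd$delta[rd$endpoint == s$endpoint[i]]
    # half-widths are 2 * SD * |delta| before clamping (no clamp at sd 0.08)
    expect_equal(s$delta_s_high[i] - s$base[i], 2 * 0.08 * dr,
                 tolerance = 1e-12)
    expect_equal(s$base[i] - s$delta_s_low[i], 2 * 0.08 * dr,
                 tolerance = 1e-12)
    expect_true(s$base[i] >= min(s$delta_s_low[i], s$delta_s_high[i]) &&
                  s$base[i] <= max(s$delta_s_low[i], s$delta_s_high[i]))
  }
  # ALI carries the largest |delta| among nonfatal endpoints: widest bar
  expect_identical(s$endpoint[1], "nonfatal_ali")
})

test_that("zero-SD endpoints do not move, and clamping only shrinks bars", {
  rd <- data.frame(endpoint = c("f", "a", "b"), delta = c(10, -50, 20))
  w <- rbind(weight_spec("f", 0, 0),
             weight_spec("a", 0.5, 0),
             weight_spec("b", 0.1, 0.3))  # weight 0.9: +2SD clamps at 1
  s <- one_way_sensitivity(rd, w)
  a <- s[s$endpoint == "a", ]
  expect_equal(a$delta_s_low, a$base)
  expect_equal(a$delta_s_high, a$base)
  b <- s[s$endpoint == "b", ]
  unclamped <- 2 * 0.3 * abs(20)
  expect_lt(abs(b$delta_s_high - b$delta_s_low), 2 * unclamped)
  expect_equal(b$delta_s_high - b$base, (1 - 0.9) * 20)   # clamped at w = 1
  expect_equal(b$base - b$delta_s_low, 2 * 0.3 * 20)      # unclamped side
})

make_two_arm <- function(n, rate_a, rate_c, seed, cens_days = 1200) {
  set.seed(seed)
  mk <- function(arm, rate, offset) {
    t_ev <- rexp(n, rate)
    keep <- t_ev * 365.25 <= cens_days
    list(p = data.frame(patient_id = offset + 1:n, arm = arm,
                        followup_end_days = cens_days, last_dose_days = 0),
         e = data.frame(patient_id = offset + (1:n)[keep], endpoint = "e",
                        time_days = t_ev[keep] * 365.25, fatal = FALSE))
  }
  a <- mk("active", rate_a, 0)
  b <- mk("control", rate_c, n)
  structure(list(patients = rbind(a$p, b$p), events = rbind(a$e, b$e)),
            class = "br_trial")
}

test_that("the temporal score reduces to the KM difference for one endpoint", {
  tr <- make_two_arm(400, 0.10, 0.25, seed = 14)
  tree <- value_tree(endpoint_spec("e", "benefit", fatal = TRUE))
  fev <- first_events(apply_scope(tr, scope_config("itt")), tree)
  grid <- seq(90, 1100, by = 91)
  tm <- temporal_mcda(fev, tree, c(e = 1), grid_days = grid, n_mc = 200)
  ka <- km_curve(fev, "e", "active")
  kc <- km_curve(fev, "e", "control")
  dc <- km_difference_curve(ka, kc, at_risk_floor = 0)
  step <- stepfun(dc$time_days[-1], dc$diff, right = FALSE)
  expect_equal(tm$delta_s_t, 1e4 * step(grid), tolerance = 1e-10)
  # constant hazards with active < control: monotone decreasing trajectory
  expect_true(all(diff(tm$delta_s_t) <= 0))
  expect_true(all(tm$ci_lo_t <= tm$delta_s_t & tm$delta_s_t <= tm$ci_hi_t))
})

test_that("identical arms give a flat zero trajectory", {
  # control arm is an exact copy of the active cohort
  tr <- make_two_arm(150, 0.2, 0.2, seed = 15)
  active <- tr$patients$patient_id <= 150
  tr$patients <- rbind(tr$patients[active, ],
                       transform(tr$patients[active, ],
                                 patient_id = patient_id + 500,
                                 arm = "control"))
  ev <- tr$events[tr$events$patient_id <= 150, ]
  tr$events <- rbind(ev, transform(ev, patient_id = patient_id + 500))
  tree <- value_tree(endpoint_spec("e", "benefit", fatal = TRUE))
  fev <- first_events(apply_scope(tr, scope_config("itt")), tree)
  tm <- temporal_mcda(fev, tree, c(e = 1), grid_days = c(100, 300, 500),
                      n_mc = 100)
  expect_true(all(tm$delta_s_t == 0))
})

test_that("grid times beyond follow-up are truncated with a warning", {
  tr <- make_two_arm(100, 0.3, 0.3, seed = 16, cens_days = 400)
  tree <- value_tree(endpoint_spec("e", "benefit", fatal = TRUE))
  fev <- first_events(apply_scope(tr, scope_config("itt")), tree)
  expect_warning(
    tm <- temporal_mcda(fev, tree, c(e = 1),
                        grid_days = c(100, 300, 900), n_mc = 100),
    "truncated")
  expect_equal(tm$grid_days, c(100, 300))
})

test_that("normal-theory bands are available and centred on the estimate", {
  tr <- make_two_arm(200, 0.15, 0.3, seed = 17)
  tree <- value_tree(endpoint_spec("e", "benefit", fatal = TRUE))
  fev <- first_events(apply_scope(tr, scope_config("itt")), tree)
  tm <- temporal_mcda(fev, tree, c(e = 1), grid_days = c(200, 400),
                      band = "normal")
  expect_identical(attr(tm, "band"), "normal")
  expect_equal((tm$ci_lo_t + tm$ci_hi_t) / 2, tm$delta_s_t)
})
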