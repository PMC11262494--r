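test_that("gamma rate draws match the count-based moments", {
  set.seed(1)
  s <- data.frame(events = 400L, patient_years = 10000)
  r <- sample_rates(s, 1e5)
  # mean 400 per 10 000 PY, variance 10^8 * d / PY^2 = 400
  se_mean <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 400), 3 * se_mean)
  expect_lt(abs(var(r) - 400) / 400, 0.10)
  # zero counts fall back to a non-degenerate Jeffreys-style gamma
  r0 <- sample_rates(data.frame(events = 0L, patient_years = 100), 1000)
  expect_true(all(r0 > 0))
  expect_gt(var(r0), 0)
})

test_that("CI-derived Gaussian draws recover the printed interval width", {
  t1 <- voyager_table1()
  rd <- aggregate_rate_table(t1)
  ali <- rd[rd$endpoint == "nonfatal_ali", ]
  expect_equal(ali$se, (-51 - (-149.6)) / 3.92, tolerance = 1e-3)
  set.seed(2)
  mc <- run_monte_carlo(ali, c(nonfatal_ali = 1),
                        config = mc_config(n_runs = 2e5, seed = 2))
  expect_lt(abs(sd(mc$draws) - ali$se) / ali$se, 0.02)
})

test_that("weight draws respect their moments and support", {
  spec <- weight_spec("x", utility_mean = 0.64, utility_sd = 0.05,
                      family = "beta")
  set.seed(3)
  w <- sample_weights(spec, 1e5)
  expect_lt(abs(mean(w) - 0.36) / 0.36, 0.01)
  expect_lt(abs(sd(w) - 0.05) / 0.05, 0.02)
  expect_true(all(w >= 0 & w <= 1))
  # fixed and zero-sd specs degenerate to the point weight
  expect_equal(sample_weights(weight_spec("x", 0.36), 10), rep(0.64, 10))
  # truncated normal stays inside [0, 1] even with a wild SD
  tn <- sample_weights(weight_spec("x", 0.9, 0.8, "truncated-normal"), 1e4)
  expect_true(all(tn >= 0 & tn <= 1))
  # infeasible beta moments are a configuration error
  expect_error(sample_weights(weight_spec("x", 0.5, 0.6, "beta"), 10),
               "infeasible beta moments")
})

test_that("degenerate draws give a point mass", {
  rd <- data.frame(endpoint = "a", delta = -5, se = 0)
  mc <- run_monte_carlo(rd, c(a = 0.5), config = mc_config(n_runs = 100))
  expect_true(mc$p_benefit %in% c(0, 1))
  expect_equal(mc$ci_hi - mc$ci_lo, 0)
  expect_equal(mc$mean_delta_s, -2.5)
  expect_error(run_monte_carlo(rd, c(a = 0.5),
                               config = mc_config(n_runs = 10)),
               "n_runs too small")
})

test_that("net-benefit probability matches the closed-form normal oracle", {
  rd <- aggregate_rate_table(voyager_table1())
  w <- setNames(voyager_table1()$weight_mean, voyager_table1()$endpoint)
  mu <- sum(w[rd$endpoint] * rd$delta)
  sig <- sqrt(sum(w[rd$endpoint]^2 * rd$se^2))
  p_cf <- pnorm(-mu / sig)
  mc <- run_monte_carlo(rd, w, config = mc_config(n_runs = 2e5, seed = 5))
  se_bin <- sqrt(p_cf * (1 - p_cf) / mc$n_runs)
  expect_lt(abs(mc$p_benefit - p_cf), 3 * se_bin)
})

test_that("the Monte Carlo mean and contributions are centred on the point fit", {
  rd <- aggregate_rate_table(voyager_table1())
  w <- voyager_weights()
  fit <- br_mcda(rd, w)
  mc <- run_monte_carlo(rd, w, config = mc_config(n_runs = 2e5, seed = 6))
  se <- sd(mc$draws) / sqrt(mc$n_runs)
  expect_lt(abs(mc$mean_delta_s - fit$score_difference), 3 * se)
  expect_equal(unname(mc$mean_contributions), unname(fit$contributions),
               tolerance = 0.05)
  expect_equal(sum(mc$mean_contributions), mc$mean_delta_s,
               tolerance = 1e-9)
})

test_that("results are seed-reproducible and seed-stable", {
  rd <- aggregate_rate_table(voyager_table1())
  w <- voyager_weights()
  m1 <- run_monte_carlo(rd, w, config = mc_config(n_runs = 5e4, seed = 7))
  m2 <- run_monte_carlo(rd, w, config = mc_config(n_runs = 5e4, seed = 7))
  expect_identical(m1$draws, m2$draws)
  m3 <- run_monte_carlo(rd, w, config = mc_config(n_runs = 5e4, seed = 8))
  se_bin <- sqrt(m1$p_benefit * (1 - m1$p_benefit) / 5e4)
  expect_lt(abs(m1$p_benefit - m3$p_benefit), 3 * sqrt(2) * se_bin)
})

test_that("inflating weight uncertainty flattens, never sharpens, the CDF", {
  rd <- aggregate_rate_table(voyager_table1())
  p_narrow <- run_monte_carlo(rd, voyager_weights(utility_sd_nonfatal = 0.02),
                              config = mc_config(n_runs = 1e5, seed = 9))$p_benefit
  p_wide <- run_monte_carlo(rd, voyager_weights(utility_sd_nonfatal = 0.12),
                            config = mc_config(n_runs = 1e5, seed = 9))$p_benefit
  se_bin <- sqrt(0.65 * 0.35 / 1e5)
  expect_lt(p_wide, p_narrow + 3 * sqrt(2) * se_bin)
})

test_that("gamma-by-counts sampling works from patient-level summaries", {
  tr <- default_trial()
  fev <- first_events(apply_scope(tr, scope_config("itt")),
                      voyager_value_tree())
  rd <- rate_table(fev, voyager_value_tree())
  mc <- run_monte_carlo(rd, voyager_weights(),
                        config = mc_config(n_runs = 5e4, seed = 10,
                                           rate_model = "gamma-by-counts"))
  fit <- br_mcda(rd, voyager_weights())
  se <- sd(mc$draws) / sqrt(mc$n_runs)
  # gamma means equal d/PY exactly, so the MC mean stays near the point fit
  expect_lt(abs(mc$mean_delta_s - fit$score_difference), 4 * se)
})

test_that("density outputs are a consistent PDF/CDF pair", {
  rd <- aggregate_rate_table(voyager_table1())
  mc <- run_monte_carlo(rd, voyager_weights(),
                        config = mc_config(n_runs = 2e4, seed = 11))
  d <- density_outputs(mc)
  expect_true(0 %in% d$x)
  expect_identical(d$cdf[d$x == 0], mc$p_benefit)
  expect_true(all(diff(d$cdf) >= 0))
  expect_equal(d$cdf[1], 0)
  expect_gte(d$cdf[nrow(d)], 1 - 2 / mc$n_runs)
  expect_error(density_outputs(rnorm(100)), "at least 1000 draws")
})
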