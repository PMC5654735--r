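test_that("generated plans match the prescribed distribution", {
  set.seed(21)
  cfg <- simulator_config(n_treatment = 10000, n_control = 0)
  co <- generate_cohort(cfg)
  # truncation at 30 of N(139, 62) shifts the mean up slightly; compare
  # against the truncated-normal mean, within 2 SE
  a <- (30 - 139) / 62
  mu_trunc <- 139 + 62 * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(co$weekly_target_minutes) - mu_trunc),
            2 * 62 / sqrt(10000))
  expect_true(all(co$weekly_target_minutes >= 30))
  # plan invariant: sessions x minutes_per_session == weekly target
  expect_true(all(co$sessions_per_week * co$minutes_per_session ==
                    co$weekly_target_minutes))
  # cluster mixture near 4:9:5 and gender-given-cluster as configured
  expect_lt(abs(mean(co$cluster == 3) - 5 / 18), 0.02)
  expect_lt(abs(mean(co$gender[co$cluster == 3] == "female") - 0.20), 0.03)
  expect_lt(abs(mean(co$gender[co$cluster == 2] == "female") - 0.667), 0.03)
})

test_that("degenerate mixtures and seeds behave deterministically", {
  cfg1 <- simulator_config(n_treatment = 50, n_control = 0,
                           cluster_weights = c(1, 1e-12, 1e-12))
  set.seed(3)
  expect_true(all(generate_cohort(cfg1)$cluster == 1))
  set.seed(4)
  c1 <- generate_cohort(simulator_config())
  set.seed(4)
  c2 <- generate_cohort(simulator_config())
  expect_identical(c1, c2)
  expect_error(generate_cohort(simulator_config(n_treatment = 0,
                                                n_control = 0)),
               "positive")
})

test_that("noise-free dynamics reduce to the planted multipliers", {
  cfg <- simulator_config(noise_sdlog = 0, cadence_sdlog = 0,
                          sequence_multipliers = matrix(
                            1, 4, 4, dimnames = list(daily_messages(),
                                                     daily_messages())))
  st <- list(cluster = 3, baseline_minutes = 40, baseline_cadence = 100)
  # neutral action: minutes equal baseline exactly
  d0 <- simulate_day(st, "none", "none", cfg)
  expect_equal(d0$minutes, 40)
  # positive_social doubles for cluster 3
  expect_equal(simulate_day(st, "positive_social", "none", cfg)$minutes, 80)
  # cluster 1: every message strictly lowers minutes versus none
  st1 <- list(cluster = 1, baseline_minutes = 40, baseline_cadence = 100)
  base <- simulate_day(st1, "none", "none", cfg)$minutes
  for (a in c("negative", "positive_self", "positive_social"))
    expect_lt(simulate_day(st1, a, "none", cfg)$minutes, base)
  # sub-bout totals are recorded as zero, with zero cadence
  st2 <- list(cluster = 2, baseline_minutes = 8, baseline_cadence = 100)
  d8 <- simulate_day(st2, "none", "none", cfg)
  expect_equal(d8$minutes, 0)
  expect_equal(d8$cadence, 0)
})

test_that("shocks scale behaviour multiplicatively and validate severity", {
  expect_equal(apply_shock(c(30, 40), 1), c(0, 0))
  expect_equal(apply_shock(c(30, 40), 0), c(30, 40))
  expect_equal(apply_shock(40, 0.5), 20)
  expect_error(apply_shock(40, 1.5), "\\[0, 1\\]")
  sched <- data.frame(day = 10, duration = 7, severity = 0.5)
  expect_equal(shock_factor(sched, 9), 1)
  expect_equal(shock_factor(sched, 10), 0.5)
  expect_equal(shock_factor(sched, 16), 0.5)
  expect_equal(shock_factor(sched, 17), 1)
  cfg <- simulator_config(noise_sdlog = 0)
  st <- list(cluster = 2, baseline_minutes = 40, baseline_cadence = 100)
  expect_equal(simulate_day(st, "none", "none", cfg, shock = 0.5)$minutes, 20)
})

test_that("equal multipliers are a negative control: actions cannot matter", {
  cfg <- simulator_config(
    cluster_multipliers = matrix(1, 3, 4,
                                 dimnames = list(NULL, daily_messages())),
    sequence_multipliers = matrix(1, 4, 4,
                                  dimnames = list(daily_messages(),
                                                  daily_messages())))
  st <- list(cluster = 2, baseline_minutes = 40, baseline_cadence = 100)
  # identical noise draw gives identical outcomes for every action
  for (a in daily_messages()) {
    d <- simulate_day(st, a, "negative", cfg, noise = 1.1, cadence_noise = 1)
    expect_equal(d$minutes, 44)
  }
})

test_that("habit drift compounds planted effects and respects its bounds", {
  cfg <- simulator_config()
  h <- 0
  for (i in 1:200) h <- update_habit(h, log(2), cfg)
  expect_lte(exp(h), cfg$habit_range[2])
  expect_gt(exp(h), 1)
  h2 <- 0
  for (i in 1:200) h2 <- update_habit(h2, log(0.5), cfg)
  expect_gte(exp(h2), cfg$habit_range[1])
  # neutral effects decay back to baseline
  h3 <- update_habit(log(1.5), 0, cfg)
  expect_lt(h3, log(1.5))
})

test_that("regression on actions recovers the planted effect ordering", {
  # within each cluster, per-action mean rewards from a randomized log must
  # rank-correlate positively with that cluster's planted multipliers
  # (mean reversion in the ratio reward reshapes the gaps but not the rank
  # direction), in nearly every replicate
  mult <- simulator_config()$cluster_multipliers
  hits <- 0
  for (s in 1:20) {
    tr <- simulate_trial(days = 180, policy = "uniform", seed = 300 + s)
    ex <- tr$examples
    ex <- ex[!is.na(ex$reward), ]
    cl <- tr$cohort$cluster[match(ex$patient_id, tr$cohort$patient_id)]
    fit <- lm(pmin(reward, 10) ~ 0 + action:factor(cl), data = ex)
    ok <- TRUE
    for (k in 1:3) {
      means <- coef(fit)[paste0("action", daily_messages(),
                                ":factor(cl)", k)]
      if (any(is.na(means))) next  # cluster absent from this small cohort
      ok <- ok && cor(means, mult[k, ], method = "spearman") > 0
    }
    hits <- hits + ok
  }
  expect_gte(hits, 19)  # > 0.95 recovery over 20 seeded replicates
})

test_that("a mid-learning shock shows up in the model stability trace", {
  tr <- simulate_trial(days = 180, seed = 5)
  mt <- model_trace(tr$snapshots)
  day <- as.integer(mt$fit_date - tr$sim_config$start_date) + 1
  sh <- tr$sim_config$shocks
  in_shock <- day >= sh$day & day <= sh$day + sh$duration
  expect_gt(max(mt$stability[in_shock], na.rm = TRUE),
            median(mt$stability[!in_shock], na.rm = TRUE))
})

test_that("HbA1c trajectory declines with accumulated walking", {
  h <- hba1c_trajectory(8.0, rep(30, 100), per_1000min = 0.05)
  expect_equal(h[100], 8.0 - 0.05 * 3000 / 1000)
  expect_true(all(diff(h) <= 0))
  expect_error(hba1c_trajectory(0, rep(30, 10)), "positive")
})
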