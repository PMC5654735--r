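test_that("feedback effectiveness matches hand arithmetic and group-by oracle", {
  d <- toy_decisions(rep("negative", 4), rep(1.0, 4))
  eff <- feedback_effectiveness(d)
  expect_equal(eff$mean_reward[eff$action == "negative"], 1.0)
  expect_equal(unique(eff$effectiveness), 1.0)
  # two-message toy log {A: rewards (1, 3), B: (2)}
  d2 <- toy_decisions(c("negative", "negative", "none"), c(1, 3, 2))
  e2 <- feedback_effectiveness(d2)
  expect_equal(e2$mean_reward[e2$action == "negative"], 2)
  expect_equal(e2$mean_reward[e2$action == "none"], 2)
  expect_equal(e2$freq[e2$action == "negative"], 2 / 3)
  expect_equal(e2$freq[e2$action == "none"], 1 / 3)
  expect_equal(unique(e2$effectiveness), 2.0)
  # unseen messages are missing, not zero
  expect_true(is.na(e2$mean_reward[e2$action == "positive_self"]))
  # order invariance
  e2p <- feedback_effectiveness(d2[c(3, 1, 2), ])
  expect_equal(e2, e2p)
  # agrees with a naive tapply oracle on a simulated log
  tr <- simulate_trial(days = 40, seed = 23)
  dd <- tr$decisions
  ok <- dd$suppression_reason == "none" & !is.na(dd$reward)
  oracle <- tapply(dd$reward[ok], dd$action[ok], mean)
  got <- feedback_effectiveness(dd)
  for (a in names(oracle))
    expect_equal(got$mean_reward[got$action == a], unname(oracle[a]))
})

test_that("sequential effects use consecutive same-patient days only", {
  d <- toy_decisions(c("negative", "positive_self"), c(NA, 1.4))
  se <- sequential_effects(d)
  expect_equal(se$mean["negative", "positive_self"], 1.4)
  expect_equal(se$n["negative", "positive_self"], 1)
  expect_equal(sum(se$n), 1)
  expect_true(all(is.na(se$mean[se$n == 0])))
  # a one-day gap breaks the pair
  dgap <- toy_decisions(c("negative", "positive_self"), c(NA, 1.4),
                        dates = as.Date("2016-01-04") + c(0, 2))
  expect_equal(sum(sequential_effects(dgap)$n), 0)
  # different patients never pair
  d2 <- rbind(toy_decisions("negative", NA, patient_id = "P01"),
              toy_decisions("positive_self", 1.4, patient_id = "P02"))
  expect_equal(sum(sequential_effects(d2)$n), 0)
})

test_that("the planted negative-then-positive-self boost is recovered", {
  tr <- simulate_trial(days = 180, policy = "uniform", seed = 24)
  se <- sequential_effects(tr$decisions)
  expect_gt(se$mean["negative", "positive_self"],
            se$mean["none", "positive_self"])
})

test_that("response vectors require two distinct messages and impute gaps", {
  d <- rbind(
    toy_decisions(c("negative", "none", "negative"), c(0.8, 1.2, 1.0),
                  patient_id = "P01"),
    toy_decisions(rep("negative", 3), c(1, 1, 1), patient_id = "P02"))
  rv <- response_vectors(d)
  expect_equal(rownames(rv$vectors), "P01")  # P02: single message type
  expect_equal(unname(rv$vectors["P01", "negative"]), 0.9)
  expect_equal(unname(rv$vectors["P01", "none"]), 1.2)
  # never-received cells imputed with the patient's own mean
  expect_equal(unname(rv$vectors["P01", "positive_self"]), mean(c(0.9, 1.2)))
  expect_equal(rv$n_imputed, 2)
})

test_that("k-means response clustering recovers planted structure", {
  set.seed(41)
  sim <- simulate_response_vectors(60, noise_sd = 0.05)
  cl <- cluster_responses(sim$vectors)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, sim$cluster), 1.0)
  # labels are ordered by centroid mean: cluster 1 reacts most negatively
  expect_true(all(diff(rowMeans(cl$centers)) > 0))
  # errors: degenerate input and too few patients
  same <- matrix(1, 10, 4)
  expect_error(cluster_responses(same), "degenerate")
  expect_error(cluster_responses(sim$vectors[1:2, ]), "fewer eligible")
})

test_that("activity slopes and fit weights follow OLS", {
  s <- activity_slope(c(0.1, 0.2, 0.3))
  expect_equal(s$slope, 0.1, tolerance = 1e-12)
  expect_equal(s$weight, 1.0)
  # noiseless line recovered exactly
  s2 <- activity_slope(0.05 + 0.013 * (1:50))
  expect_equal(s2$slope, 0.013, tolerance = 1e-12)
  # pure noise: weight near zero, so it barely moves a weighted mean
  set.seed(55)
  s3 <- activity_slope(rnorm(500))
  expect_lt(s3$weight, 0.05)
  expect_error(activity_slope(c(1)), "at least 2")
  expect_error(activity_slope(c(1, 2), index = c(3, 3)), "constant")
  # fit-weighted group mean
  expect_equal(group_slope(c(0.01, -0.5), c(1, 0)), 0.01)
})

test_that("cadence slopes use weekly means and drop non-walking weeks", {
  expect_equal(cadence_slope(rep(100, 8))$slope, 0)
  ramp <- seq(100, 110, length.out = 10)
  expect_equal(cadence_slope(ramp)$slope, 10 / 9, tolerance = 1e-12)
  # zero-walking weeks are excluded, not treated as cadence 0
  with_gap <- c(100, 0, 104, 106, 108)
  expect_equal(cadence_slope(with_gap)$slope, 2, tolerance = 1e-12)
})

test_that("model trace computes the magnitude-change stability statistic", {
  m1 <- manual_model(); m2 <- manual_model()
  m1$coef[] <- 0; m2$coef[] <- 0
  m1$coef[1:2] <- c(1, -1); m2$coef[1:2] <- c(2, -1)
  m1$intercept <- 0; m2$intercept <- 0
  m1$fit_date <- as.Date("2016-04-05"); m2$fit_date <- as.Date("2016-04-06")
  tr <- model_trace(list(m1, m2))
  expect_true(is.na(tr$stability[1]))
  expect_equal(tr$stability[2], 1.0)
  # identical snapshots give zero change
  expect_equal(model_trace(list(m1, m1))$stability[2], 0)
  # a pure sign flip leaves magnitudes unchanged
  m3 <- m1; m3$coef[1:2] <- c(-1, 1)
  expect_equal(model_trace(list(m1, m3))$stability[2], 0)
  # manifest mismatch rejected
  m4 <- m2; m4$manifest <- rev(m4$manifest)
  expect_error(model_trace(list(m1, m4)), "manifest")
  expect_error(model_trace(list(m1)), "at least 2")
})

test_that("relative HbA1c reduction follows the printed formula", {
  expect_equal(relative_hba1c_reduction(8.0, 8.0), 0.0)
  expect_equal(relative_hba1c_reduction(8.0, 7.2), 0.1)
  expect_equal(relative_hba1c_reduction(7.0, 7.7), -0.1)
  expect_error(relative_hba1c_reduction(0, 7), "positive")
})

test_that("the full report assembles on a simulated trial", {
  cfg <- engine_config(initial_phase_days = 10, min_examples = 60)
  tr <- simulate_trial(days = 35, config = cfg, seed = 27)
  rep <- evaluate_trial(tr)
  expect_s3_class(rep, "coach_report")
  expect_true(all(c("treatment", "control") %in% names(rep$activity_slopes)))
  expect_equal(dim(rep$sequential$mean), c(4, 4))
  expect_true(!is.null(rep$trace))
  f <- tempfile(fileext = ".json")
  write_report(rep, f)
  expect_true(file.exists(f))
  expect_silent(jsonlite::read_json(f))
  unlink(f)
})
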