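test_that("reward ratio handles unchanged, doubled and zero-activity days", {
  expect_equal(compute_reward(30, 30), 1.0)
  expect_equal(compute_reward(30, 60, epsilon = 0), 2.0)
  expect_equal(compute_reward(0, 30, epsilon = 1), 31.0)
  expect_equal(compute_reward(0, 0), 1.0)
  expect_error(compute_reward(-1, 30), ">= 0")
  expect_error(compute_reward(0, 30, epsilon = 0), "epsilon")
})

test_that("context features assemble goal fractions and message recency", {
  mon <- as.Date("2016-01-04")
  pat <- patient("P01", 61, "female", activity_plan(140, 3, 47),
                 "treatment", mon)
  hist <- data.frame(date = mon + 0:5, minutes = c(20, 10, 0, 15, 10, 15))
  log <- data.frame(date = c(mon + 4, mon + 5),
                    action = c("positive_self", "negative"))
  x <- build_features(pat, hist, log, mon + 6)  # Sunday, day 7 of the week
  expect_equal(unname(x["cum_week_minutes"]), 70)
  expect_equal(unname(x["frac_goal"]), 0.5)
  expect_equal(unname(x["frac_vs_expected"]), 0.5)  # expected fraction is 1
  expect_equal(unname(x["minutes_last_day"]), 15)
  expect_equal(unname(x["ds_negative"]), 1)       # sent yesterday morning
  expect_equal(unname(x["ds_positive_self"]), 2)
  expect_equal(unname(x["ds_positive_social"]), 30)  # never sent: capped
  expect_equal(unname(x["gender_female"]), 1)
  expect_error(build_features(list(age = 60, gender = "male"), hist, log, mon),
               "plan")
})

test_that("Kesler augmentation appends a correct one-hot block", {
  x <- random_context()
  r <- kesler_augment(x, "negative")
  expect_length(r, 14)
  expect_equal(unname(r[11:14]), c(1, 0, 0, 0))
  r2 <- kesler_augment(x, "none")
  expect_equal(unname(r2[11:14]), c(0, 0, 0, 1))
  expect_equal(r[1:10], r2[1:10])  # same context, different block only
  expect_equal(sum(r[11:14]), 1)
})

test_that("interaction expansion matches a brute-force double-loop oracle", {
  set.seed(99)
  for (a in daily_messages()) {
    row <- kesler_augment(random_context(), a)
    got <- expand_interactions(row)
    want <- naive_expand(row)
    expect_length(got, 99)
    expect_equal(got, want)
  }
  # all-zero base row expands to all zeros
  z <- expand_interactions(rep(0, 14))
  expect_true(all(z == 0))
  # matrix form agrees with row-by-row expansion
  X <- rbind(kesler_augment(random_context(), "negative"),
             kesler_augment(random_context(), "positive_social"))
  M <- expand_interactions(X)
  expect_equal(dim(M), c(2L, 99L))
  expect_equal(M[2, ], expand_interactions(X[2, ]))
})

test_that("ridge fit matches plain least squares on a well-posed instance", {
  set.seed(5)
  n <- 120
  X <- matrix(rnorm(n * 10), n, 10)
  colnames(X) <- paste0("c", 1:10)
  beta <- rnorm(10)
  y <- 0.5 + drop(X %*% beta) + rnorm(n, 0, 0.1)
  fit <- fit_ridge(X, y, lambda = 1e-10)
  ref <- lm(y ~ X)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-8)
  expect_equal(unname(fit$coef), unname(coef(ref)[-1]), tolerance = 1e-8)
  # and matches the literal penalized normal equations at lambda = 1e-3
  lam <- 1e-3
  Xm <- cbind(1, X)
  s <- sqrt(colMeans(Xm^2))
  A <- crossprod(Xm) + diag(c(0, n * lam * s[-1]^2))
  b_oracle <- drop(solve(A, crossprod(Xm, y)))
  fit2 <- fit_ridge(X, y, lambda = lam)
  expect_equal(c(fit2$intercept, fit2$coef), unname(b_oracle),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("noiseless data are reproduced exactly and contrasts identified", {
  set.seed(17)
  n <- 400
  X <- t(replicate(n, random_context()))
  acts <- sample(daily_messages(), n, replace = TRUE)
  K <- outer(acts, daily_messages(), "==") * 1
  D <- expand_interactions(cbind(X, K))
  # scale planted effects by column size so the noiseless response stays a
  # positive, reward-like quantity
  beta_true <- rnorm(99, 0, 0.05) / sqrt(colMeans(D^2))
  y_true <- 2 + drop(D %*% beta_true)
  stopifnot(min(y_true) > 0)
  m <- fit_model(X, acts, y_true, lambda = 1e-10, reward_cap = Inf,
                 min_n = 100)
  fitted <- m$intercept + drop(D %*% m$coef)
  expect_equal(fitted, y_true, tolerance = 1e-6)
  # identified action contrasts match the planted ones at a reference context
  x0 <- random_context()
  for (a in c("negative", "positive_social")) {
    d_true <- sum((expand_interactions(kesler_augment(x0, a)) -
                     expand_interactions(kesler_augment(x0, "none"))) * beta_true)
    got <- action_contrast(m, x0, a)$estimate
    expect_equal(got, d_true, tolerance = 1e-6)
  }
  # refit determinism: identical data give identical coefficients
  m2 <- fit_model(X, acts, y_true, lambda = 1e-10, reward_cap = Inf,
                  min_n = 100)
  expect_identical(m$coef, m2$coef)
})

test_that("too few examples signal insufficient data", {
  X <- t(replicate(50, random_context()))
  expect_error(fit_model(X, rep("none", 50), rep(1, 50)), "insufficient data")
})

test_that("gain prediction equals term-by-term evaluation", {
  m0 <- manual_model(intercept = 1)
  x <- random_context()
  for (a in daily_messages()) expect_equal(predict_gain(m0, x, a), 1.0)
  # a single positive_social main effect traces through
  m1 <- manual_model(intercept = 1)
  m1$coef["a_positive_social"] <- 0.3
  expect_equal(predict_gain(m1, x, "positive_social"), 1.3)
  expect_equal(predict_gain(m1, x, "negative"), 1.0)
  # arbitrary model vs naive oracle
  set.seed(31)
  m2 <- manual_model(coef = rnorm(99), intercept = rnorm(1))
  for (a in daily_messages()) {
    row <- naive_expand(kesler_augment(x, a))
    naive <- m2$intercept + sum(m2$coef * row)
    expect_equal(predict_gain(m2, x, a), naive, tolerance = 1e-10)
  }
  # manifest mismatch is rejected
  m3 <- m2
  m3$manifest <- rev(m3$manifest)
  expect_error(predict_gain(m3, x, "none"), "manifest")
})

test_that("adjusted R^2 approaches its theoretical value on model-true data", {
  set.seed(77)
  n <- 5000
  X <- t(replicate(n, random_context()))
  acts <- sample(daily_messages(), n, replace = TRUE)
  D <- expand_interactions(cbind(X, outer(acts, daily_messages(), "==") * 1))
  beta_true <- rnorm(99, 0, 0.05) / sqrt(colMeans(D^2))
  signal <- 2 + drop(D %*% beta_true)
  y <- signal + rnorm(n, 0, 0.2)
  stopifnot(min(y) > 0)
  m <- fit_model(X, acts, y, reward_cap = Inf, min_n = 100)
  r2_theory <- var(signal) / (var(signal) + 0.04)
  expect_lt(abs(m$adj_r2 - r2_theory), 0.05)
})

test_that("Boltzmann probabilities are normalized, shift-invariant, monotone", {
  p <- boltzmann_probs(c(1, 1, 1, 1), 5)
  expect_equal(unname(p), rep(0.25, 4))
  p2 <- boltzmann_probs(c(2, 0, 0, 0), 5)
  expect_equal(unname(p2[1]), exp(0.4) / (exp(0.4) + 3), tolerance = 1e-12)
  # high-temperature limit is uniform
  expect_equal(unname(boltzmann_probs(c(2, 0, 1, 0.5), 1e6)), rep(0.25, 4),
               tolerance = 1e-6)
  # shift invariance
  g <- c(0.8, 1.2, 1.9, 1.0)
  expect_equal(boltzmann_probs(g, 5), boltzmann_probs(g + 100, 5))
  expect_equal(sum(boltzmann_probs(g, 5)), 1, tolerance = 1e-12)
  # raising one gain strictly raises its probability
  g2 <- g; g2[2] <- g2[2] + 0.5
  expect_gt(boltzmann_probs(g2, 5)[2], boltzmann_probs(g, 5)[2])
  expect_error(boltzmann_probs(c(1, NA, 1, 1), 5), "finite")
  expect_error(boltzmann_probs(g, 0), "> 0")
})

test_that("Boltzmann sampling follows its analytic distribution", {
  g <- c(negative = 0.8, positive_self = 1.5, positive_social = 1.9, none = 1.0)
  set.seed(12)
  draws <- replicate(20000, boltzmann_sample(g, 5))
  p <- boltzmann_probs(g, 5)
  obs <- table(factor(draws, levels = names(g)))
  chi <- suppressWarnings(stats::chisq.test(obs, p = p))
  expect_gt(chi$p.value, 0.001)
})

test_that("model snapshots round-trip through JSON", {
  set.seed(2)
  m <- manual_model(coef = rnorm(99), intercept = 1.2)
  m$n <- 500; m$adj_r2 <- 0.31; m$fit_date <- as.Date("2016-04-05")
  f <- tempfile(fileext = ".json")
  write_model_snapshot(m, f)
  back <- read_model_snapshot(f)
  expect_equal(back$coef, m$coef)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$adj_r2, 0.31)
  x <- random_context()
  expect_equal(predict_gain(back, x, "negative"),
               predict_gain(m, x, "negative"), tolerance = 1e-12)
  unlink(f)
})
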