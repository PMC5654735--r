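# The contextual-bandit learner: reward, daily-refit interaction regression,
# gain prediction and Boltzmann exploration.

#' Day-over-day activity-change reward
#'
#' The reward attached to a daily decision is the ratio of walking minutes on
#' the message day to those on the previous day, regularized by `epsilon`
#' minutes so zero-activity days remain defined:
#' `(minutes_next + epsilon) / (minutes_t + epsilon)`. A value above 1 means
#' activity increased. `epsilon = 0` gives the raw ratio.
#'
#' @param minutes_t minutes on the reference day (>= 0, vectorized).
#' @param minutes_next minutes on the following (message) day (>= 0).
#' @param epsilon regularization minutes (default 1).
#' @return reward ratio(s), finite and >= 0.
#' @export
compute_reward <- function(minutes_t, minutes_next, epsilon = 1) {
  if (any(minutes_t < 0) || any(minutes_next < 0))
    stop("minutes must be >= 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (epsilon == 0 && any(minutes_t == 0))
    stop("raw ratio undefined for minutes_t == 0; use epsilon > 0")
  (minutes_next + epsilon) / (minutes_t + epsilon)
}

#' Ridge-stabilized least squares on an explicit design matrix
#'
#' Solves the normal equations with a small ridge penalty applied on the
#' scale of each column's root-mean-square (so `lambda` is meaningful across
#' raw feature scales) and proportional to `n`; the intercept is not
#' penalized. As `n` grows the penalty's influence vanishes and the fit
#' approaches plain least squares; its role is rank-deficiency robustness
#' early in learning (the full Kesler-plus-interactions design is exactly
#' collinear: the one-hot block sums to the intercept).
#'
#' @param D design matrix (n x p, no intercept column).
#' @param y response vector.
#' @param lambda ridge penalty (default 1e-6).
#' @return list with `intercept`, `coef` (length p), and `vcov_unscaled`
#'   (the (p+1) x (p+1) matrix `Ainv %*% XtX %*% Ainv` whose diagonal times
#'   the residual variance gives squared standard errors).
#' @export
fit_ridge <- function(D, y, lambda = 1e-6) {
  n <- nrow(D)
  Dm <- cbind(1, D)
  s <- sqrt(colMeans(Dm^2))
  s[s == 0] <- 1
  # solve in the column-RMS-scaled basis for conditioning; the penalty is
  # n * lambda on each scaled column (none on the intercept), which is
  # n * lambda * s_j^2 on the raw scale
  Ds <- sweep(Dm, 2, s, "/")
  XtXs <- crossprod(Ds)
  pen <- rep(n * lambda, ncol(Ds))
  pen[1] <- 0  # intercept unpenalized
  As <- XtXs + diag(pen, nrow = length(pen))
  Ainv <- solve(As)
  bs <- drop(Ainv %*% crossprod(Ds, y))
  # one step of iterative refinement: the normal equations square the
  # condition number, and near-zero penalties leave ~1e-5 residual error
  r <- y - drop(Ds %*% bs)
  bs <- bs + drop(Ainv %*% (crossprod(Ds, r) - pen * bs))
  beta <- bs / s
  V <- Ainv %*% XtXs %*% Ainv
  vcov_unscaled <- sweep(sweep(V, 1, s, "/"), 2, s, "/")
  list(intercept = unname(beta[1]),
       coef = stats::setNames(beta[-1], colnames(D)),
       vcov_unscaled = vcov_unscaled)
}

#' Fit the daily interaction-expanded regression model
#'
#' Builds the Kesler-augmented, interaction-expanded design from the stored
#' training examples and fits the ridge-stabilized least squares of
#' [fit_ridge()]. Rewards are winsorized at `reward_cap` before fitting to
#' bound the leverage of near-zero-denominator ratios. Refitting on
#' identical data reproduces identical coefficients.
#'
#' @param features numeric matrix (n x 10) of context features, columns in
#'   [feature_names()] order, or a data frame of examples with those columns
#'   plus `action` and `reward`.
#' @param actions character vector of daily actions (ignored when `features`
#'   is an example data frame).
#' @param rewards numeric reward vector (ignored likewise).
#' @param lambda ridge penalty (default 1e-6).
#' @param reward_cap winsorization cap applied to rewards before fitting
#'   (default 10; `Inf` disables).
#' @param min_n minimum number of examples; fewer signals insufficient data
#'   (default 200) so the engine stays on the initial policy.
#' @return object of class `bandit_model`: coefficients over the 99 design
#'   columns, intercept, column manifest, `n`, `r2`, `adj_r2`, residual
#'   variance `sigma2` and coefficient covariance (for contrast SEs).
#' @export
fit_model <- function(features, actions = NULL, rewards = NULL,
                      lambda = 1e-6, reward_cap = 10, min_n = 200) {
  if (is.data.frame(features)) {
    actions <- features$action
    rewards <- features$reward
    features <- as.matrix(features[, feature_names()])
  }
  n <- nrow(features)
  if (n < min_n)
    stop("insufficient data: ", n, " examples < minimum ", min_n)
  if (length(actions) != n || length(rewards) != n)
    stop("features, actions and rewards must have matching lengths")
  if (any(!actions %in% daily_messages())) stop("unknown action in training data")
  if (any(!is.finite(rewards)) || any(rewards < 0))
    stop("rewards must be finite and >= 0")
  y <- pmin(rewards, reward_cap)
  K <- outer(actions, daily_messages(), "==") * 1
  D <- expand_interactions(cbind(features, K))
  fit <- fit_ridge(D, y, lambda)
  fitted <- drop(cbind(1, D) %*% c(fit$intercept, fit$coef))
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  p <- ncol(D)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (tss > 0 && n > p + 1) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  sigma2 <- if (n > p + 1) rss / (n - p - 1) else NA_real_
  structure(
    list(intercept = fit$intercept,
         coef = stats::setNames(fit$coef, colnames(D)),
         manifest = colnames(D),
         n = n, p = p, r2 = r2, adj_r2 = adj_r2, sigma2 = sigma2,
         lambda = lambda, reward_cap = reward_cap,
         vcov_unscaled = fit$vcov_unscaled,
         fit_date = NA),
    class = "bandit_model")
}

#' @export
print.bandit_model <- function(x, ...) {
  cat("bandit_model:", x$p, "design columns, n =", x$n,
      sprintf(", adj R^2 = %.3f\n", x$adj_r2))
  invisible(x)
}

#' Predicted next-day activity gain for a context and action
#'
#' Evaluates the fitted model on the interaction-expanded Kesler row for
#' `(x, action)`: the predicted reward ratio if that message were sent.
#'
#' @param model a fitted [fit_model()] object.
#' @param x context feature vector (length 10).
#' @param action one of [daily_messages()].
#' @return predicted reward ratio (scalar).
#' @export
predict_gain <- function(model, x, action) {
  row <- expand_interactions(kesler_augment(x, action))
  if (!identical(names(row), model$manifest))
    stop("model manifest does not match the design layout")
  drop(model$intercept + sum(model$coef * row))
}

# Predicted gains for every action for a batch of contexts.
# X: n x 10 matrix. Returns n x 4 matrix (columns = daily_messages()).
predict_gains_matrix <- function(model, X) {
  n <- nrow(X)
  msgs <- daily_messages()
  out <- matrix(NA_real_, n, 4, dimnames = list(NULL, msgs))
  for (j in seq_along(msgs)) {
    K <- matrix(0, n, 4)
    K[, j] <- 1
    D <- expand_interactions(cbind(X, K))
    out[, j] <- model$intercept + drop(D %*% model$coef)
  }
  out
}

#' Estimated effect of an action versus a reference action at a context
#'
#' Because the full one-hot Kesler design is collinear with the intercept,
#' individual action coefficients are not identified; differences between
#' actions at a given context are. This returns the identified contrast
#' `predict(x, action) - predict(x, ref)` with its standard error from the
#' coefficient covariance.
#'
#' @param model a fitted [fit_model()] object.
#' @param x context feature vector (length 10).
#' @param action,ref daily actions to compare (default ref `"none"`).
#' @return list with `estimate` and `se`.
#' @export
action_contrast <- function(model, x, action, ref = "none") {
  r1 <- expand_interactions(kesler_augment(x, action))
  r0 <- expand_interactions(kesler_augment(x, ref))
  cvec <- c(0, r1 - r0)
  est <- sum(cvec[-1] * model$coef)
  se <- if (is.finite(model$sigma2))
    sqrt(model$sigma2 * drop(t(cvec) %*% model$vcov_unscaled %*% cvec))
  else NA_real_
  list(estimate = est, se = se)
}

#' Boltzmann (softmax) action probabilities
#'
#' `P(a) = exp(gain_a / T) / sum_b exp(gain_b / T)`, computed with the
#' maximum gain subtracted for numerical stability (the distribution is
#' invariant to shifting all gains).
#'
#' @param gains numeric vector of predicted gains, one per action (finite).
#' @param temperature Boltzmann temperature T > 0 (default 5, the value used
#'   throughout and never adapted).
#' @return probability vector summing to 1 (names preserved).
#' @export
boltzmann_probs <- function(gains, temperature = 5) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  if (any(!is.finite(gains))) stop("gains must be finite")
  z <- gains / temperature
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Sample an action by Boltzmann exploration
#'
#' @inheritParams boltzmann_probs
#' @return one of [daily_messages()] (or `names(gains)` when supplied).
#' @export
boltzmann_sample <- function(gains, temperature = 5) {
  p <- boltzmann_probs(gains, temperature)
  nm <- names(gains) %||% daily_messages()[seq_along(gains)]
  nm[sample.int(length(p), 1, prob = p)]
}

#' Write / read a model snapshot as JSON
#'
#' One snapshot per refit day (manifest, coefficients, intercept, n,
#' adjusted R^2, fit date) enables the day-to-day stability trace of
#' [model_trace()].
#'
#' @param model a `bandit_model`.
#' @param path JSON file path.
#' @return `read_model_snapshot`: a `bandit_model` (without covariance).
#' @export
write_model_snapshot <- function(model, path) {
  jsonlite::write_json(
    list(manifest = model$manifest,
         intercept = model$intercept,
         coef = unname(model$coef),
         n = model$n, r2 = model$r2, adj_r2 = model$adj_r2,
         lambda = model$lambda, reward_cap = model$reward_cap,
         fit_date = as.character(model$fit_date)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_snapshot
#' @export
read_model_snapshot <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(intercept = s$intercept,
         coef = stats::setNames(s$coef, s$manifest),
         manifest = s$manifest,
         n = s$n, p = length(s$manifest), r2 = s$r2, adj_r2 = s$adj_r2,
         sigma2 = NA_real_, lambda = s$lambda, reward_cap = s$reward_cap,
         vcov_unscaled = NULL, fit_date = s$fit_date),
    class = "bandit_model")
}
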