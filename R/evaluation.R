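# Results-section analyses applied to decision logs (simulated or
# real-format): message effectiveness, sequential effects, response
# clustering, fit-weighted slopes, model traces, and glycemic change.

#' Per-message improvement and probability-weighted effectiveness
#'
#' For each policy phase in the log: the mean activity-change reward
#' following each daily message, the empirical send frequency of each
#' message, and the feedback effectiveness — the per-message means weighted
#' by the empirical message probabilities. Messages never selected in a
#' phase are reported as missing, not zero. Only decisions with a finalized
#' reward contribute; the output is invariant to row order.
#'
#' @param decisions decision log data frame with columns `phase`, `action`,
#'   `reward`, `suppression_reason`.
#' @return data frame with one row per (phase, action) holding `mean_reward`,
#'   `n`, `freq`, plus an attached attribute-free summary row per phase via
#'   the `effectiveness` column (repeated within phase).
#' @export
feedback_effectiveness <- function(decisions) {
  ok <- decisions$suppression_reason == "none" & !is.na(decisions$reward)
  d <- decisions[ok, , drop = FALSE]
  if (nrow(d) == 0) stop("no finalized decisions in log")
  out <- do.call(rbind, lapply(split(d, d$phase), function(g) {
    n <- vapply(daily_messages(), function(a) sum(g$action == a), 0)
    mean_r <- vapply(daily_messages(), function(a) {
      x <- g$reward[g$action == a]
      if (length(x)) mean(x) else NA_real_
    }, 0)
    freq <- n / sum(n)
    eff <- sum(freq[n > 0] * mean_r[n > 0])
    data.frame(phase = g$phase[1], action = daily_messages(),
               mean_reward = mean_r, n = n, freq = freq,
               effectiveness = eff, stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Sequential message effects
#'
#' Mean activity-change reward on day N by the pair (message on day N-1,
#' message on day N), over consecutive-day decision pairs of the same
#' patient on which an action was taken both days; days separated by a gap
#' contribute to no cell. Note that on logs produced by the learned policy
#' the pairs are algorithm-chosen, not randomized, so the table is
#' descriptive rather than causal.
#'
#' @param decisions decision log data frame.
#' @return list with `mean` and `n`: 4 x 4 matrices indexed by (previous
#'   action, current action); cells with no observations are `NA` (0 in
#'   `n`).
#' @export
sequential_effects <- function(decisions) {
  msgs <- daily_messages()
  s <- matrix(0, 4, 4, dimnames = list(msgs, msgs))
  n <- matrix(0, 4, 4, dimnames = list(msgs, msgs))
  ok <- decisions$suppression_reason == "none"
  d <- decisions[ok, , drop = FALSE]
  d <- d[order(d$patient_id, as.Date(d$date)), , drop = FALSE]
  for (g in split(d, d$patient_id)) {
    if (nrow(g) < 2) next
    gap <- as.integer(diff(as.Date(g$date)))
    cur <- 2:nrow(g)
    use <- gap == 1 & !is.na(g$reward[cur])
    for (k in cur[use]) {
      p <- g$action[k - 1L]; c_ <- g$action[k]
      s[p, c_] <- s[p, c_] + g$reward[k]
      n[p, c_] <- n[p, c_] + 1
    }
  }
  m <- s / n
  m[n == 0] <- NA_real_
  list(mean = m, n = n)
}

#' Per-patient message-response vectors
#'
#' Represents each patient by the mean activity-change reward following each
#' of the four daily messages. Only patients who received at least two
#' distinct message types are eligible; cells for messages a patient never
#' received are imputed with that patient's mean over observed cells (noted
#' in `n_imputed`).
#'
#' @param decisions decision log data frame.
#' @param reward_cap winsorization cap applied to rewards before averaging,
#'   as in model fitting (default 10; `Inf` for raw ratios).
#' @return list with `vectors` (eligible patients x 4 matrix, rownames =
#'   patient ids), `counts` (same shape, observation counts) and
#'   `n_imputed`.
#' @export
response_vectors <- function(decisions, reward_cap = 10) {
  ok <- decisions$suppression_reason == "none" & !is.na(decisions$reward)
  d <- decisions[ok, , drop = FALSE]
  d$reward <- pmin(d$reward, reward_cap)
  ids <- unique(d$patient_id)
  V <- matrix(NA_real_, length(ids), 4, dimnames = list(ids, daily_messages()))
  Nc <- matrix(0, length(ids), 4, dimnames = list(ids, daily_messages()))
  for (g in split(d, d$patient_id)) {
    id <- g$patient_id[1]
    for (a in unique(g$action)) {
      x <- g$reward[g$action == a]
      V[id, a] <- mean(x)
      Nc[id, a] <- length(x)
    }
  }
  eligible <- rowSums(Nc > 0) >= 2
  V <- V[eligible, , drop = FALSE]
  Nc <- Nc[eligible, , drop = FALSE]
  n_imp <- sum(is.na(V))
  for (i in seq_len(nrow(V))) {
    miss <- is.na(V[i, ])
    if (any(miss)) V[i, miss] <- mean(V[i, !miss])
  }
  list(vectors = V, counts = Nc, n_imputed = n_imp)
}

#' Cluster patients by message response
#'
#' k-means (k = 3 by default, 50 random restarts) on the per-patient
#' response vectors, with clusters relabeled in ascending order of centroid
#' mean response so labels are deterministic and cluster 1 is always the
#' most negatively reacting group.
#'
#' @param vectors numeric matrix, one row per eligible patient (see
#'   [response_vectors()]).
#' @param k number of clusters (default 3).
#' @param nstart random restarts (default 50).
#' @return list with `cluster` (relabeled assignments), `centers`
#'   (relabeled centroids) and `sizes`.
#' @export
cluster_responses <- function(vectors, k = 3, nstart = 50) {
  if (nrow(vectors) < k)
    stop("fewer eligible patients (", nrow(vectors), ") than clusters (", k, ")")
  if (all(apply(vectors, 2, stats::var) < 1e-12))
    stop("degenerate clustering: all response vectors are identical")
  km <- stats::kmeans(vectors, centers = k, nstart = nstart)
  ord <- order(rowMeans(km$centers))
  relabel <- match(seq_len(k), ord)
  list(cluster = relabel[km$cluster],
       centers = km$centers[ord, , drop = FALSE],
       sizes = km$size[ord])
}

#' Ordinary least-squares slope of an activity series with fit weight
#'
#' Fits value ~ index by OLS and returns the slope together with the R^2 of
#' the fit, which serves as the weight when averaging slopes across a policy
#' group ("weighted by the fit of the linear function").
#'
#' @param values series of daily fraction-of-target activity (or weekly
#'   cadence means for [cadence_slope()]).
#' @param index time index (default `seq_along(values)`).
#' @return list with `slope`, `weight` (R^2, clamped to \[0, 1\]; 1 for an
#'   exact line, defined as 1 when the series is constant) and `n`.
#' @export
activity_slope <- function(values, index = seq_along(values)) {
  keep <- !is.na(values)
  values <- values[keep]; index <- index[keep]
  n <- length(values)
  if (n < 2) stop("need at least 2 points to fit a slope")
  if (stats::var(index) == 0) stop("time index is constant")
  slope <- stats::cov(index, values) / stats::var(index)
  fitted <- mean(values) + slope * (index - mean(index))
  tss <- sum((values - mean(values))^2)
  r2 <- if (tss > 0) 1 - sum((values - fitted)^2) / tss else 1
  list(slope = slope, weight = min(max(r2, 0), 1), n = n)
}

#' @rdname activity_slope
#' @param weekly_cadence weekly mean steps-per-minute series; weeks with no
#'   qualifying walking (cadence `NA` or 0) are excluded.
#' @export
cadence_slope <- function(weekly_cadence) {
  idx <- seq_along(weekly_cadence)
  keep <- !is.na(weekly_cadence) & weekly_cadence > 0
  activity_slope(weekly_cadence[keep], idx[keep])
}

#' Fit-weighted group mean slope
#'
#' @param slopes,weights vectors of per-patient slopes and fit weights.
#' @return weighted mean slope.
#' @export
group_slope <- function(slopes, weights) {
  if (sum(weights) == 0) return(NA_real_)
  sum(slopes * weights) / sum(weights)
}

#' Day-to-day model stability and adjusted-R^2 traces
#'
#' Stability on refit day d is the summed difference of the absolute values
#' of the model parameters between successive days,
#' `sum_j | |beta_j(d)| - |beta_j(d-1)| |` (intercept included); a sign flip
#' with unchanged magnitude therefore contributes 0. The adjusted-R^2 trace
#' is copied from the snapshots.
#'
#' @param snapshots list of `bandit_model` snapshots (successive refit
#'   days, identical manifests).
#' @return data frame with `fit_date`, `stability` (`NA` for the first
#'   snapshot) and `adj_r2`.
#' @export
model_trace <- function(snapshots) {
  if (length(snapshots) < 2) stop("need at least 2 snapshots")
  man <- lapply(snapshots, `[[`, "manifest")
  if (!all(vapply(man, identical, TRUE, man[[1]])))
    stop("snapshot manifests differ between days")
  B <- vapply(snapshots, function(s) abs(c(s$intercept, s$coef)),
              numeric(length(man[[1]]) + 1))
  stab <- c(NA_real_, colSums(abs(B[, -1, drop = FALSE] -
                                    B[, -ncol(B), drop = FALSE])))
  data.frame(
    fit_date = as.Date(vapply(snapshots, function(s) as.character(s$fit_date), "")),
    stability = stab,
    adj_r2 = vapply(snapshots, function(s) s$adj_r2 %||% NA_real_, 0))
}

#' Relative reduction in glycated hemoglobin
#'
#' `(HbA1c[0] - HbA1c[t]) / HbA1c[0]`; positive values mean improvement
#' (lower HbA1c, better glycemic control).
#'
#' @param h0 HbA1c at the start of the experiment (%), > 0.
#' @param ht HbA1c at time t (%).
#' @return relative reduction (fraction).
#' @export
relative_hba1c_reduction <- function(h0, ht) {
  if (any(h0 <= 0)) stop("h0 must be positive")
  (h0 - ht) / h0
}

#' Full evaluation report for a simulated trial
#'
#' Runs the analysis battery on a `coach_trial`: per-message effectiveness
#' by phase, the sequential-effects table, response clustering (when enough
#' eligible patients), fit-weighted activity and cadence slopes per
#' arm/phase group, and the model stability/adjusted-R^2 traces.
#'
#' @param trial a [simulate_trial()] result.
#' @param k clusters for the response clustering.
#' @return list of class `coach_report`.
#' @export
evaluate_trial <- function(trial, k = 3) {
  dec <- trial$decisions
  eff <- feedback_effectiveness(dec)
  seqe <- sequential_effects(dec)
  rv <- response_vectors(dec)
  clus <- if (nrow(rv$vectors) >= k) cluster_responses(rv$vectors, k) else NULL

  # per-patient slope of daily fraction-of-target activity
  target_daily <- trial$cohort$weekly_target_minutes / 7
  frac <- sweep(trial$minutes, 1, target_daily, "/")
  slopes <- lapply(seq_len(nrow(frac)), function(i) activity_slope(frac[i, ]))
  sl <- vapply(slopes, `[[`, 0, "slope")
  wt <- vapply(slopes, `[[`, 0, "weight")
  arm <- trial$cohort$arm
  act_slopes <- c(treatment = group_slope(sl[arm == "treatment"], wt[arm == "treatment"]),
                  control = group_slope(sl[arm == "control"], wt[arm == "control"]))

  # weekly cadence slopes
  nweeks <- ncol(trial$minutes) %/% 7
  cad_group <- rep(NA_real_, 2)
  names(cad_group) <- c("treatment", "control")
  if (nweeks >= 2) {
    wc <- sapply(seq_len(nweeks), function(k2) {
      cols <- (7 * k2 - 6):(7 * k2)
      apply(trial$cadence[, cols, drop = FALSE], 1, function(x) {
        x <- x[x > 0]
        if (length(x)) mean(x) else NA_real_
      })
    })
    cs <- lapply(seq_len(nrow(wc)), function(i) {
      ok <- sum(!is.na(wc[i, ]) & wc[i, ] > 0) >= 2
      if (ok) cadence_slope(wc[i, ]) else list(slope = NA_real_, weight = 0)
    })
    csl <- vapply(cs, `[[`, 0, "slope")
    cwt <- vapply(cs, `[[`, 0, "weight")
    use <- !is.na(csl)
    for (a in c("treatment", "control")) {
      g <- use & arm == a
      if (any(g)) cad_group[a] <- group_slope(csl[g], cwt[g])
    }
  }

  trace <- if (length(trial$snapshots) >= 2) model_trace(trial$snapshots) else NULL
  structure(
    list(effectiveness = eff, sequential = seqe,
         response_vectors = rv, clusters = clus,
         activity_slopes = act_slopes, cadence_slopes = cad_group,
         trace = trace),
    class = "coach_report")
}

#' Write an evaluation report as JSON
#'
#' @param report a [evaluate_trial()] result.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  out <- list(
    effectiveness = report$effectiveness,
    sequential_mean = report$sequential$mean,
    sequential_n = report$sequential$n,
    clusters = report$clusters,
    activity_slopes = as.list(report$activity_slopes),
    cadence_slopes = as.list(report$cadence_slopes),
    trace = report$trace)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}
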