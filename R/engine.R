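# Daily orchestration: phase selection, staleness guard, decision and reward
# bookkeeping, weekly summaries with achievement cooldown, and the closed
# simulation loop.

#' Engine configuration
#'
#' @param initial_phase_days length of the initial (predetermined) policy
#'   phase; the learned policy takes over afterwards, provided enough
#'   training examples have accumulated (default 90 days, i.e. 3 months).
#' @param staleness_hours suppress SMS when no device data was received for
#'   this many hours or more before decision time (default 12, inclusive
#'   boundary).
#' @param achievement_cooldown_days minimum days between weekly achievement
#'   messages for one patient (default 21).
#' @param temperature Boltzmann temperature of the learned policy (default
#'   5; fixed, never adapted).
#' @param p_no_message initial policy's no-message probability (default 0.2).
#' @param min_examples minimum finalized training examples before the
#'   learned phase activates (default 200).
#' @param ds_cap cap on the days-since-message features (default 30).
#' @param epsilon reward regularization minutes (default 1; see
#'   [compute_reward()]).
#' @param reward_cap winsorization cap on rewards before fitting (default 10).
#' @param lambda ridge penalty of the daily refit (default 1e-6).
#' @param decision_hour hour of day (UTC) at which decisions are made
#'   (default 8, i.e. each morning).
#' @return list of class `engine_config`.
#' @export
engine_config <- function(initial_phase_days = 90, staleness_hours = 12,
                          achievement_cooldown_days = 21, temperature = 5,
                          p_no_message = 0.2, min_examples = 200,
                          ds_cap = 30, epsilon = 1, reward_cap = 10,
                          lambda = 1e-6, decision_hour = 8) {
  if (initial_phase_days <= 0 || staleness_hours <= 0 ||
      achievement_cooldown_days <= 0 || temperature <= 0)
    stop("all durations and the temperature must be positive")
  structure(as.list(environment()), class = "engine_config")
}

#' Staleness guard for SMS sending
#'
#' Messages are suppressed for patients whose data were not received within
#' the staleness window before the current time, to avoid feedback based on
#' missing data: suppress iff
#' `decision_time - last_transmission >= staleness_hours` (the boundary is
#' inclusive: a gap of exactly 12 hours suppresses).
#'
#' @param last_transmission timestamp(s) of the most recent data upload.
#' @param decision_time the current (decision) timestamp.
#' @param staleness_hours threshold in hours (default 12).
#' @return character vector, `"send"` or `"suppress"` per patient.
#' @export
staleness_guard <- function(last_transmission, decision_time,
                            staleness_hours = 12) {
  gap <- as.numeric(difftime(decision_time, last_transmission, units = "hours"))
  if (any(gap < 0)) stop("last_transmission is in the future")
  ifelse(gap >= staleness_hours, "suppress", "send")
}

#' Select the weekly summary message for one patient
#'
#' The weekly "increase" is this week's total minutes minus the previous
#' week's. Achievement messages require an eligible increase and a clear
#' cooldown (at least `cooldown_days` since the last achievement), with
#' precedence maximal_increase > maximal_social > significant_increase >
#' significant_social; otherwise (and always for the control arm) the fixed
#' weekly reminder is sent. `maximal_increase` requires strictly exceeding
#' every one of the patient's previous weekly increases (so at least one
#' previous increase, i.e. three completed weeks, must exist);
#' `significant_increase` requires strictly exceeding their median. The
#' social variants compare this week's increase with the other participants'
#' increases this week (strictly greatest, resp. strictly above their
#' median).
#'
#' @param weekly_minutes the patient's completed weekly totals, oldest
#'   first.
#' @param others_increases other participants' week-over-week increases for
#'   the current week.
#' @param days_since_achievement days since this patient's last achievement
#'   message (`Inf` if never).
#' @param arm `"treatment"` or `"control"`.
#' @param cooldown_days achievement cooldown (default 21).
#' @return one of [weekly_messages()].
#' @export
weekly_summary <- function(weekly_minutes, others_increases = numeric(0),
                           days_since_achievement = Inf,
                           arm = "treatment", cooldown_days = 21) {
  if (arm == "control") return("reminder")
  w <- length(weekly_minutes)
  if (w < 2) return("reminder")
  inc <- diff(weekly_minutes)
  cur <- inc[length(inc)]
  prev <- inc[-length(inc)]
  if (days_since_achievement < cooldown_days) return("reminder")
  if (length(prev) >= 1 && cur > max(prev)) return("maximal_increase")
  if (length(others_increases) >= 1 && cur > max(others_increases))
    return("maximal_social")
  if (length(prev) >= 1 && cur > stats::median(prev))
    return("significant_increase")
  if (length(others_increases) >= 1 && cur > stats::median(others_increases))
    return("significant_social")
  "reminder"
}

#' Initialize engine state for a trial
#'
#' @param cohort cohort data frame (see [generate_cohort()] or
#'   [read_cohort_csv()]).
#' @param config an [engine_config()].
#' @param policy `"adaptive"` (initial phase then learned),
#'   `"initial"` (initial policy throughout), `"uniform"` (uniform random
#'   over the four actions; comparison baseline) or `"none"` (no daily
#'   messages).
#' @param max_days capacity to preallocate.
#' @param start_date first study day.
#' @return opaque engine state list; advance it with [observe_day()] and
#'   [run_day()].
#' @export
new_trial_state <- function(cohort, config = engine_config(),
                            policy = c("adaptive", "initial", "uniform", "none"),
                            max_days = 400, start_date = min(cohort$enrolled_on)) {
  policy <- match.arg(policy)
  np <- nrow(cohort)
  cap <- np * max_days
  list(
    cohort = cohort, config = config, policy = policy,
    start_date = as.Date(start_date), max_days = max_days,
    last_decision_date = as.Date(NA),
    minutes = matrix(NA_real_, np, max_days),
    cadence = matrix(NA_real_, np, max_days),
    lt = matrix(as.POSIXct(NA), np, max_days),
    last_transmission = rep(as.POSIXct(paste(as.Date(start_date), "06:00:00"),
                                       tz = "UTC"), np),
    cum_week = numeric(np),
    ds = matrix(config$ds_cap, np, 4, dimnames = list(NULL, daily_messages())),
    prev_action = rep("none", np),
    pending_ex = rep(NA_integer_, np),
    pending_dec = rep(NA_integer_, np),
    last_ach_day = rep(-Inf, np),
    model = NULL, snapshots = list(),
    ex_features = matrix(NA_real_, cap, 10,
                         dimnames = list(NULL, feature_names())),
    ex_action = character(cap), ex_reward = rep(NA_real_, cap),
    ex_patient = character(cap), ex_day = integer(cap), ex_n = 0L,
    dec_patient = character(cap), dec_date = rep(as.Date(NA), cap),
    dec_day = integer(cap), dec_phase = character(cap),
    dec_action = character(cap), dec_sent = logical(cap),
    dec_reason = character(cap), dec_text = character(cap),
    dec_reward = rep(NA_real_, cap), dec_n = 0L,
    weekly = list(),
    eff_action = rep("none", np))
}

#' Ingest one day of observed activity into the engine state
#'
#' Records each patient's measured walking for `date` together with the
#' timestamp of their most recent data upload (which determines freshness at
#' the next morning's decision).
#'
#' @param state engine state from [new_trial_state()].
#' @param date the activity date.
#' @param minutes,cadence numeric vectors, one entry per cohort row.
#' @param last_transmission `POSIXct` vector of upload times.
#' @return updated state.
#' @export
observe_day <- function(state, date, minutes, cadence, last_transmission) {
  d <- as.integer(as.Date(date) - state$start_date) + 1L
  if (d < 1 || d > state$max_days) stop("date outside trial capacity")
  state$minutes[, d] <- minutes
  state$cadence[, d] <- cadence
  state$last_transmission <- as.POSIXct(last_transmission, tz = "UTC")
  state$lt[, d] <- state$last_transmission
  state$cum_week <- state$cum_week + minutes
  state
}

# completed weekly totals matrix (patients x weeks) through day `upto`
completed_weekly_totals <- function(minutes, upto) {
  nweeks <- upto %/% 7
  if (nweeks < 1) return(NULL)
  sapply(seq_len(nweeks), function(k)
    rowSums(minutes[, (7 * k - 6):(7 * k), drop = FALSE]))
}

#' Run one morning of the intervention engine
#'
#' For each patient: finalize yesterday's reward if fresh data arrived;
#' on Mondays, issue the weekly summary messages; apply the staleness
#' guard; select the daily action by the current policy phase (initial
#' stochastic policy, or the Boltzmann-sampled learned policy once the
#' initial phase has elapsed and enough examples are available, refit each
#' morning); render and log the decision. Control-arm patients receive no
#' daily message. Running the same date twice is an error.
#'
#' @param state engine state (with observations through yesterday ingested
#'   via [observe_day()]).
#' @param date the decision date.
#' @return updated state; today's effective actions are in
#'   `state$eff_action`.
#' @export
run_day <- function(state, date) {
  date <- as.Date(date)
  if (!is.na(state$last_decision_date) && date <= state$last_decision_date)
    stop("run_day already executed for ", date, " (duplicate run)")
  cfg <- state$config
  np <- nrow(state$cohort)
  d <- as.integer(date - state$start_date) + 1L
  decision_time <- as.POSIXct(sprintf("%s %02d:00:00", date, cfg$decision_hour),
                              tz = "UTC")
  treatment <- state$cohort$arm == "treatment"
  target <- state$cohort$weekly_target_minutes

  # Monday: a new plan week begins (cumulative counter restarts before any
  # of today's data exists), and completed weeks are summarized.
  if (weekday_index(date) == 1) {
    state$cum_week <- numeric(np)
    if (d > 7) state <- issue_weekly_summaries(state, date, d)
  }

  guard <- staleness_guard(state$last_transmission, decision_time,
                           cfg$staleness_hours)
  fresh <- guard == "send"

  # finalize yesterday's pending rewards where fresh data arrived
  pend <- which(!is.na(state$pending_ex))
  for (i in pend) {
    if (fresh[i]) {
      m_prev <- state$minutes[i, d - 1L]
      m_prevprev <- if (d >= 3) state$minutes[i, d - 2L] else 0
      r <- compute_reward(m_prevprev, m_prev, cfg$epsilon)
      state$ex_reward[state$pending_ex[i]] <- r
      state$dec_reward[state$pending_dec[i]] <- r
    }
    # stale: the example for that gap is never emitted
  }
  state$pending_ex[] <- NA_integer_
  state$pending_dec[] <- NA_integer_

  n_valid <- sum(!is.na(state$ex_reward[seq_len(state$ex_n)]))
  learned <- state$policy == "adaptive" && d > cfg$initial_phase_days &&
    n_valid >= cfg$min_examples
  if (learned) {
    valid <- which(!is.na(state$ex_reward[seq_len(state$ex_n)]))
    model <- fit_model(state$ex_features[valid, , drop = FALSE],
                       state$ex_action[valid], state$ex_reward[valid],
                       lambda = cfg$lambda, reward_cap = cfg$reward_cap,
                       min_n = cfg$min_examples)
    model$fit_date <- date
    state$model <- model
    state$snapshots[[length(state$snapshots) + 1L]] <- model
  }

  acted <- treatment & fresh & state$policy != "none"
  # context features for acting patients (data through yesterday)
  F <- NULL
  if (any(acted)) {
    ia <- which(acted)
    ml <- if (d >= 2) state$minutes[ia, d - 1L] else numeric(length(ia))
    ml[is.na(ml)] <- 0
    cw <- state$cum_week[ia]
    fg <- cw / target[ia]
    fve <- fg / expected_fraction(date)
    F <- cbind(ml, cw, fg, fve, state$cohort$age[ia],
               as.numeric(state$cohort$gender[ia] == "female"),
               state$ds[ia, , drop = FALSE])
    colnames(F) <- feature_names()

    actions <- if (learned) {
      gains <- predict_gains_matrix(state$model, F)
      z <- gains / cfg$temperature
      z <- z - apply(z, 1, max)
      P <- exp(z)
      P <- P / rowSums(P)
      cp <- t(apply(P, 1, cumsum))
      u <- stats::runif(length(ia))
      daily_messages()[1L + rowSums(u > cp)]
    } else if (state$policy == "uniform") {
      sample(daily_messages(), length(ia), replace = TRUE)
    } else {
      choose_action_initial(rep(expected_fraction(date), length(ia)),
                            initial_policy_config(cfg$p_no_message))
    }
  }

  phase_label <- if (state$policy %in% c("adaptive", "initial"))
    (if (learned) "learned" else "initial") else state$policy

  # log decisions for every patient
  eff <- rep("none", np)
  for (i in seq_len(np)) {
    k <- state$dec_n + 1L
    state$dec_n <- k
    state$dec_patient[k] <- state$cohort$patient_id[i]
    state$dec_date[k] <- date
    state$dec_day[k] <- d
    state$dec_phase[k] <- phase_label
    if (!treatment[i]) {
      state$dec_action[k] <- "none"; state$dec_sent[k] <- FALSE
      state$dec_reason[k] <- "control_arm"; state$dec_text[k] <- ""
      next
    }
    if (!fresh[i]) {
      state$dec_action[k] <- "none"; state$dec_sent[k] <- FALSE
      state$dec_reason[k] <- "stale_data"; state$dec_text[k] <- ""
      next
    }
    if (state$policy == "none") {
      state$dec_action[k] <- "none"; state$dec_sent[k] <- FALSE
      state$dec_reason[k] <- "none"; state$dec_text[k] <- ""
      next
    }
    j <- match(i, which(acted))
    a <- actions[j]
    eff[i] <- a
    pct <- as.integer(round_half_up(100 * state$cum_week[i] / target[i]))
    state$dec_action[k] <- a
    state$dec_sent[k] <- a != "none"
    state$dec_reason[k] <- "none"
    state$dec_text[k] <- render_daily_message(a, pct)
    # emit the training example (reward pending until tomorrow morning)
    e <- state$ex_n + 1L
    state$ex_n <- e
    state$ex_features[e, ] <- F[j, ]
    state$ex_action[e] <- a
    state$ex_patient[e] <- state$cohort$patient_id[i]
    state$ex_day[e] <- d
    state$pending_ex[i] <- e
    state$pending_dec[i] <- k
  }

  # roll the days-since-message features for tomorrow; an action taken this
  # morning (including an explicit "none") resets its own counter to 1
  state$ds <- pmin(state$ds + 1, cfg$ds_cap)
  for (i in which(acted)) state$ds[i, eff[i]] <- 1
  state$prev_action <- eff
  state$eff_action <- eff
  state$last_decision_date <- date
  state
}

issue_weekly_summaries <- function(state, date, d) {
  cfg <- state$config
  W <- completed_weekly_totals(state$minutes, d - 1L)
  if (is.null(W)) return(state)
  if (is.null(dim(W))) W <- matrix(W, nrow = nrow(state$cohort))
  nweeks <- ncol(W)
  inc_cur <- if (nweeks >= 2) W[, nweeks] - W[, nweeks - 1L] else
    rep(NA_real_, nrow(W))
  for (i in seq_len(nrow(state$cohort))) {
    others <- inc_cur[-i]
    others <- others[!is.na(others)]
    msg <- weekly_summary(W[i, ], others,
                          days_since_achievement = d - state$last_ach_day[i],
                          arm = state$cohort$arm[i],
                          cooldown_days = cfg$achievement_cooldown_days)
    if (msg != "reminder") state$last_ach_day[i] <- d
    state$weekly[[length(state$weekly) + 1L]] <- data.frame(
      patient_id = state$cohort$patient_id[i], date = date,
      message = msg, text = render_weekly_message(msg),
      stringsAsFactors = FALSE)
  }
  state
}

#' Simulate a full closed-loop trial
#'
#' Generates a synthetic cohort, then alternates the morning decision engine
#' ([run_day()]) with the behaviour simulator for `days` days. All
#' environment randomness (day noise, cadence noise, transmission gaps) is
#' pre-drawn from `seed` before the loop, so two trials with the same seed
#' but different policies face identical patients and identical days — a
#' paired comparison — and replaying a seed reproduces the decision log
#' exactly.
#'
#' @param days trial length in days (default 180).
#' @param policy see [new_trial_state()].
#' @param sim_config a [simulator_config()].
#' @param config an [engine_config()].
#' @param seed integer RNG seed.
#' @param cohort optionally, a pre-generated cohort (latent columns
#'   required).
#' @return object of class `coach_trial`: cohort, activity log, decision
#'   log, training examples, model snapshots, weekly messages.
#' @examples
#' tr <- simulate_trial(days = 21, seed = 1)
#' head(trial_decisions(tr))
#' @export
simulate_trial <- function(days = 180,
                           policy = c("adaptive", "initial", "uniform", "none"),
                           sim_config = simulator_config(),
                           config = engine_config(), seed = 1,
                           cohort = NULL) {
  policy <- match.arg(policy)
  set.seed(seed)
  if (is.null(cohort)) cohort <- generate_cohort(sim_config)
  np <- nrow(cohort)

  # pre-drawn environment randomness (common across policies per seed)
  eps <- matrix(stats::rlnorm(np * days, 0, sim_config$noise_sdlog), np, days)
  ceps <- matrix(stats::rlnorm(np * days, 0, sim_config$cadence_sdlog), np, days)
  gap_hours <- matrix(stats::runif(np * (days + 1),
                                   sim_config$normal_gap_hours_range[1],
                                   sim_config$normal_gap_hours_range[2]),
                      np, days + 1)
  long <- matrix(stats::runif(np * (days + 1)) < sim_config$gap_prob,
                 np, days + 1)
  gap_hours[long] <- stats::runif(sum(long), sim_config$gap_hours_range[1],
                                  sim_config$gap_hours_range[2])

  state <- new_trial_state(cohort, config, policy, max_days = days + 1,
                           start_date = sim_config$start_date)
  start <- sim_config$start_date
  dtime <- function(t) as.POSIXct(sprintf("%s %02d:00:00", start + (t - 1),
                                          config$decision_hour), tz = "UTC")
  state$last_transmission <- dtime(1) - gap_hours[, 1] * 3600

  cm <- sim_config$cluster_multipliers
  sm <- sim_config$sequence_multipliers
  prev_eff <- rep("none", np)
  log_habit <- numeric(np)
  for (t in seq_len(days)) {
    date <- start + (t - 1)
    state <- run_day(state, date)
    # environment: today's behaviour under the effective actions
    aidx <- match(state$eff_action, daily_messages())
    pidx <- match(prev_eff, daily_messages())
    sf <- shock_factor(sim_config$shocks, t)
    mult <- cm[cbind(cohort$cluster, aidx)]
    seqm <- sm[cbind(pidx, aidx)]
    base <- cohort$baseline_minutes * exp(log_habit)
    raw <- if (sim_config$model == "multiplicative") {
      base * mult * seqm * sf * eps[, t]
    } else {
      pmax(base * sf + base * (mult * seqm - 1), 0) * eps[, t]
    }
    log_habit <- update_habit(log_habit, log(mult * seqm), sim_config)
    m <- round(pmax(raw, 0))
    m[m < sim_config$min_bout_minutes] <- 0
    cad <- ifelse(m > 0,
                  cohort$baseline_cadence * mult^sim_config$cadence_effect_exp *
                    ceps[, t], 0)
    lt <- dtime(t + 1) - gap_hours[, t + 1] * 3600
    state <- observe_day(state, date, m, cad, lt)
    prev_eff <- state$eff_action
  }

  structure(
    list(cohort = cohort,
         decisions = trial_decisions_from_state(state),
         examples = trial_examples_from_state(state),
         activity = trial_activity_from_state(state, days),
         snapshots = state$snapshots,
         weekly = if (length(state$weekly)) do.call(rbind, state$weekly) else NULL,
         minutes = state$minutes[, seq_len(days), drop = FALSE],
         cadence = state$cadence[, seq_len(days), drop = FALSE],
         policy = policy, seed = seed, days = days,
         sim_config = sim_config, config = config),
    class = "coach_trial")
}

trial_decisions_from_state <- function(state) {
  n <- state$dec_n
  if (n == 0) return(NULL)
  idx <- seq_len(n)
  data.frame(patient_id = state$dec_patient[idx],
             date = state$dec_date[idx], day = state$dec_day[idx],
             phase = state$dec_phase[idx], action = state$dec_action[idx],
             sent = state$dec_sent[idx],
             suppression_reason = state$dec_reason[idx],
             text = state$dec_text[idx], reward = state$dec_reward[idx],
             stringsAsFactors = FALSE)
}

trial_examples_from_state <- function(state) {
  n <- state$ex_n
  if (n == 0) return(NULL)
  idx <- seq_len(n)
  out <- as.data.frame(state$ex_features[idx, , drop = FALSE])
  out$action <- state$ex_action[idx]
  out$reward <- state$ex_reward[idx]
  out$patient_id <- state$ex_patient[idx]
  out$day <- state$ex_day[idx]
  out
}

trial_activity_from_state <- function(state, days) {
  np <- nrow(state$cohort)
  data.frame(
    patient_id = rep(state$cohort$patient_id, days),
    date = rep(state$start_date + seq_len(days) - 1, each = np),
    minutes = as.vector(state$minutes[, seq_len(days)]),
    cadence = as.vector(state$cadence[, seq_len(days)]),
    last_transmission = as.POSIXct(as.vector(state$lt[, seq_len(days)]),
                                   tz = "UTC", origin = "1970-01-01"),
    stringsAsFactors = FALSE)
}

#' Accessors for the parts of a simulated trial
#'
#' @param trial a `coach_trial` from [simulate_trial()].
#' @return the decision log, training-example log, or activity log as a
#'   data frame.
#' @export
trial_decisions <- function(trial) trial$decisions

#' @rdname trial_decisions
#' @export
trial_examples <- function(trial) trial$examples

#' @rdname trial_decisions
#' @export
trial_activity <- function(trial) trial$activity

#' @export
print.coach_trial <- function(x, ...) {
  cat("coach_trial:", nrow(x$cohort), "patients,", x$days, "days, policy =",
      x$policy, ", seed =", x$seed, "\n")
  cat("  decisions:", nrow(x$decisions), " examples:",
      sum(!is.na(x$examples$reward)), "finalized\n")
  invisible(x)
}
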