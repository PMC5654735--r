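# Synthetic cohort generator and daily behaviour model.
#
# The generator emulates a small cohort of sedentary type 2 diabetes
# patients with personal weekly walking plans (mean 139, SD 62 min/week),
# heterogeneous cluster-structured responses to the four daily messages,
# day-sequence effects, occasional transmission gaps (to exercise the
# staleness guard) and behaviour-disrupting shocks such as adverse weather.
# Behaviour is multiplicative-lognormal by default: next-day minutes =
# baseline x cluster-specific message multiplier x sequence multiplier x
# shock factor x lognormal noise, quantized to whole minutes with totals
# under 10 minutes recorded as 0 (only contiguous walks of >= 10 minutes
# count).

#' Simulator configuration
#'
#' Defaults encode the emulated study conditions: 20 treatment and 7 control
#' patients; weekly plans drawn from a truncated normal with mean 139 and SD
#' 62 minutes (minimum 30), split into 3 sessions; three response clusters
#' mixed 4:9:5 — cluster 1 reacts negatively to every message, cluster 2
#' weakly, cluster 3 strongly and positively with positive-social strongest
#' — with the female share per cluster at 50%/67%/20%; and one week-long
#' baseline shock emulating an adverse weather event at trial day 150,
#' i.e. around day 60 of the learned policy's operation, where it is
#' visible in the daily refit's stability trace.
#'
#' Cluster multiplier rows are `(negative, positive_self, positive_social,
#' none)` next-day activity multipliers; `baseline_scale` scales each
#' cluster's baseline daily minutes relative to `plan / 7`, making response
#' cluster membership partially visible to the learner through observed
#' activity levels (responders walk more), alongside the gender signal.
#'
#' @param n_treatment,n_control arm sizes.
#' @param plan_mean,plan_sd,plan_min weekly plan distribution (minutes).
#' @param sessions_per_week sessions each plan is divided into.
#' @param cluster_weights mixture weights for the 3 response clusters
#'   (normalized internally).
#' @param p_female_by_cluster P(female | cluster).
#' @param cluster_multipliers 3 x 4 matrix of next-day activity multipliers
#'   by (cluster, daily message).
#' @param baseline_scale per-cluster baseline scale relative to `plan / 7`.
#' @param baseline_sdlog patient-level lognormal dispersion of baselines.
#' @param noise_sdlog day-to-day lognormal noise SD (log scale).
#' @param sequence_multipliers 4 x 4 multiplier table keyed by (previous
#'   action, current action); defaults boost negative followed by
#'   positive-self and damp repeated positive-social.
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param cadence_mean,cadence_sd baseline walking cadence (steps/minute).
#' @param cadence_effect_exp exponent coupling the message multiplier to
#'   cadence (cadence responds more weakly than volume).
#' @param cadence_sdlog day-to-day cadence noise (log scale).
#' @param gap_prob probability that a day's data has not reached the server
#'   by the next decision time (long transmission gap).
#' @param gap_hours_range hours since last transmission for a long gap.
#' @param normal_gap_hours_range likewise for normal operation (uploads
#'   roughly every 2.5 hours).
#' @param min_bout_minutes daily totals below this are recorded as 0.
#' @param habit_kappa adherence drift: fraction of each day's planted
#'   message effect (on the log scale) that persists in the patient's habit
#'   level, so systematically helpful messages compound into lasting
#'   activity change rather than reverting overnight (default 0.10; 0
#'   disables the channel and makes behaviour stationary).
#'   With the default decay 0.05 the habit equilibrates within ~3 weeks at
#'   `exp(2 * E[log effect])` times baseline.
#' @param habit_decay daily relaxation of the habit level back toward the
#'   patient's own baseline (default 0.05).
#' @param habit_range hard bounds on the habit multiplier (default
#'   \[0.5, 2.5\] times baseline).
#' @param shocks data frame `day, duration, severity`: baseline multiplied
#'   by `1 - severity` during `[day, day + duration - 1]`.
#' @param hba1c_mean,hba1c_sd initial HbA1c distribution (%).
#' @param hba1c_per_1000min HbA1c percentage-point reduction per 1000
#'   cumulative walking minutes (demo glycemic channel; config, not a
#'   claim).
#' @param model `"multiplicative"` (default) or `"additive"` (effects add
#'   as baseline fractions; for sensitivity analyses).
#' @param start_date first study day (a Monday by default so simulated
#'   weeks align with plan weeks).
#' @return list of class `simulator_config`.
#' @export
simulator_config <- function(
    n_treatment = 20, n_control = 7,
    plan_mean = 139, plan_sd = 62, plan_min = 30, sessions_per_week = 3,
    cluster_weights = c(4, 9, 5),
    p_female_by_cluster = c(0.50, 0.667, 0.20),
    cluster_multipliers = rbind(
      c(0.75, 0.80, 0.80, 1.00),
      c(0.90, 1.05, 1.10, 1.00),
      c(0.70, 1.60, 2.00, 1.00)),
    baseline_scale = c(0.9, 1.2, 1.6),
    baseline_sdlog = 0.2,
    noise_sdlog = 0.25,
    sequence_multipliers = NULL,
    age_mean = 57, age_sd = 7, age_range = c(35, 75),
    cadence_mean = 95, cadence_sd = 10,
    cadence_effect_exp = 0.3, cadence_sdlog = 0.05,
    gap_prob = 0.05,
    gap_hours_range = c(12, 48),
    normal_gap_hours_range = c(0.5, 4),
    min_bout_minutes = 10,
    habit_kappa = 0.10, habit_decay = 0.05, habit_range = c(0.5, 2.5),
    shocks = data.frame(day = 150, duration = 7, severity = 0.6),
    hba1c_mean = 7.8, hba1c_sd = 1.0, hba1c_per_1000min = 0.05,
    model = c("multiplicative", "additive"),
    start_date = as.Date("2016-01-04")) {
  model <- match.arg(model)
  if (n_treatment <= 0 || n_control < 0) stop("arm sizes must be positive")
  if (any(cluster_weights <= 0)) stop("cluster mixture weights must be positive")
  if (noise_sdlog < 0 || baseline_sdlog < 0 || cadence_sdlog < 0)
    stop("noise SDs must be >= 0")
  dimnames(cluster_multipliers) <- list(NULL, daily_messages())
  if (is.null(sequence_multipliers)) {
    sequence_multipliers <- matrix(1, 4, 4,
                                   dimnames = list(daily_messages(), daily_messages()))
    sequence_multipliers["negative", "positive_self"] <- 1.2
    sequence_multipliers["positive_social", "positive_social"] <- 0.85
  }
  structure(as.list(environment()), class = "simulator_config")
}

# draw from normal truncated below at `lo`
rtrunc_norm <- function(n, mean, sd, lo) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic cohort with latent response states
#'
#' Draws patients with plans, demographics, arm assignment, response-cluster
#' membership and latent baselines. Latent columns (`cluster`,
#' `baseline_minutes`, `baseline_cadence`, `hba1c0`) are hidden from the
#' policies — only activity observations are exposed to the engine — and are
#' written to disk only on request (see [write_cohort_csv()]).
#'
#' @param config a [simulator_config()].
#' @return data frame, one row per patient, treatment arm first.
#' @export
generate_cohort <- function(config = simulator_config()) {
  n <- config$n_treatment + config$n_control
  if (n <= 0) stop("cohort size must be positive")
  w <- config$cluster_weights / sum(config$cluster_weights)
  cluster <- sample.int(3, n, replace = TRUE, prob = w)
  gender <- ifelse(stats::runif(n) < config$p_female_by_cluster[cluster],
                   "female", "male")
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  target_raw <- rtrunc_norm(n, config$plan_mean, config$plan_sd, config$plan_min)
  mps <- round_half_up(target_raw / config$sessions_per_week)
  target <- mps * config$sessions_per_week
  baseline <- config$baseline_scale[cluster] * (target / 7) *
    stats::rlnorm(n, 0, config$baseline_sdlog)
  cadence <- rtrunc_norm(n, config$cadence_mean, config$cadence_sd, 40)
  hba1c0 <- rtrunc_norm(n, config$hba1c_mean, config$hba1c_sd, 6.5)
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    age = round(age, 1),
    gender = gender,
    arm = rep(c("treatment", "control"), c(config$n_treatment, config$n_control)),
    weekly_target_minutes = target,
    sessions_per_week = config$sessions_per_week,
    minutes_per_session = mps,
    enrolled_on = config$start_date,
    cluster = cluster,
    baseline_minutes = baseline,
    baseline_cadence = cadence,
    hba1c0 = hba1c0,
    stringsAsFactors = FALSE)
}

#' Shock factor applied to baselines on a given study day
#'
#' @param shocks shock schedule data frame (`day`, `duration`, `severity`).
#' @param day study day (1-based).
#' @return multiplicative factor in \[0, 1\] (1 outside every shock window).
#' @export
shock_factor <- function(shocks, day) {
  if (is.null(shocks) || nrow(shocks) == 0) return(1)
  if (any(shocks$severity < 0 | shocks$severity > 1))
    stop("shock severity must be in [0, 1]")
  f <- 1
  for (k in seq_len(nrow(shocks))) {
    if (day >= shocks$day[k] && day <= shocks$day[k] + shocks$duration[k] - 1)
      f <- f * (1 - shocks$severity[k])
  }
  f
}

#' Apply a shock to a vector of baselines
#'
#' @param baselines numeric baseline minutes.
#' @param severity shock severity in \[0, 1\]; 1 shuts activity down
#'   completely, 0 leaves behaviour unchanged.
#' @return baselines multiplied by `1 - severity`.
#' @export
apply_shock <- function(baselines, severity) {
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  baselines * (1 - severity)
}

#' Simulate one patient-day of walking
#'
#' Minutes are `baseline * message multiplier * sequence multiplier * shock
#' * lognormal noise`, rounded to whole minutes, with totals below the
#' minimum qualifying bout recorded as 0. Cadence follows an analogous,
#' weaker multiplicative model and is 0 on days without qualifying walking.
#'
#' @param state one row of a [generate_cohort()] data frame (latent state).
#' @param action today's daily message (one of [daily_messages()]).
#' @param prev_action yesterday's daily message (`"none"` if none).
#' @param config a [simulator_config()].
#' @param shock factor from [shock_factor()] for today.
#' @param habit current habit multiplier (adherence drift state; default 1).
#' @param noise,cadence_noise optional pre-drawn lognormal noise values
#'   (drawn internally from the current RNG when `NULL`).
#' @return list with `minutes` (integer) and `cadence` (steps/minute).
#' @export
simulate_day <- function(state, action, prev_action = "none",
                         config = simulator_config(), shock = 1, habit = 1,
                         noise = NULL, cadence_noise = NULL) {
  action <- match.arg(action, daily_messages())
  prev_action <- match.arg(prev_action, daily_messages())
  if (is.null(noise)) noise <- stats::rlnorm(1, 0, config$noise_sdlog)
  if (is.null(cadence_noise))
    cadence_noise <- stats::rlnorm(1, 0, config$cadence_sdlog)
  mult <- config$cluster_multipliers[state$cluster, action]
  seqm <- config$sequence_multipliers[prev_action, action]
  base <- state$baseline_minutes * habit
  raw <- if (config$model == "multiplicative") {
    base * mult * seqm * shock * noise
  } else {
    pmax(base * shock + base * (mult * seqm - 1), 0) * noise
  }
  minutes <- round(pmax(raw, 0))
  if (minutes < config$min_bout_minutes) minutes <- 0
  cadence <- if (minutes > 0)
    state$baseline_cadence * mult^config$cadence_effect_exp * cadence_noise
  else 0
  list(minutes = as.numeric(minutes), cadence = cadence)
}

#' Synthetic per-patient message-response vectors at default separation
#'
#' Draws patients from the cluster mixture and returns each patient's
#' 4-dimensional mean activity-change-per-message vector: the cluster's
#' planted multipliers plus independent Gaussian noise of size `noise_sd`
#' (the sampling error of a per-message mean at trial scale, roughly
#' `noise / sqrt(days per message)`). Used to test the response clustering
#' at the separation the simulator's defaults produce.
#'
#' @param n number of patients.
#' @param config a [simulator_config()].
#' @param noise_sd SD of the per-cell noise (default 0.08).
#' @return list with `vectors` (n x 4 matrix) and `cluster` (true labels).
#' @export
simulate_response_vectors <- function(n, config = simulator_config(),
                                      noise_sd = 0.08) {
  w <- config$cluster_weights / sum(config$cluster_weights)
  cl <- sample.int(3, n, replace = TRUE, prob = w)
  V <- config$cluster_multipliers[cl, , drop = FALSE] +
    matrix(stats::rnorm(n * 4, 0, noise_sd), n, 4)
  colnames(V) <- daily_messages()
  list(vectors = V, cluster = cl)
}

#' Advance the adherence-drift (habit) state by one day
#'
#' The habit multiplier evolves on the log scale: a fraction `habit_kappa`
#' of today's planted message effect persists, while the level relaxes
#' toward baseline at rate `habit_decay`, clamped to `habit_range`.
#'
#' @param log_habit current log habit level (vector).
#' @param log_effect today's planted log message effect,
#'   `log(multiplier * sequence multiplier)` (vector).
#' @param config a [simulator_config()].
#' @return updated log habit level.
#' @export
update_habit <- function(log_habit, log_effect, config = simulator_config()) {
  h <- (1 - config$habit_decay) * log_habit + config$habit_kappa * log_effect
  pmin(pmax(h, log(config$habit_range[1])), log(config$habit_range[2]))
}

#' Latent HbA1c trajectory from accumulated walking
#'
#' A deliberately simple demo channel: glycated hemoglobin declines linearly
#' with cumulative walking minutes from its initial value,
#' `h(t) = h0 - hba1c_per_1000min * cumulative_minutes(t) / 1000`, enabling
#' end-to-end demonstrations of [relative_hba1c_reduction()]. The effect
#' size is configuration, not a claim.
#'
#' @param h0 initial HbA1c (%).
#' @param daily_minutes vector of daily walking minutes.
#' @param per_1000min percentage-point reduction per 1000 minutes.
#' @return vector of HbA1c values after each day.
#' @export
hba1c_trajectory <- function(h0, daily_minutes, per_1000min = 0.05) {
  if (h0 <= 0) stop("h0 must be positive")
  h0 - per_1000min * cumsum(daily_minutes) / 1000
}
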