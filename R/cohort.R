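#' The four daily feedback messages
#'
#' The daily action space of the coaching system, in its fixed index order.
#' The order matters: it defines the positions of the one-hot action block
#' used by the learned policy ([kesler_augment()]) and of the
#' `days_since_message` features.
#'
#' The messages correspond to the three achievement-goal framings plus a
#' no-message condition: `negative` (performance avoidance), `positive_self`
#' (mastery), `positive_social` (performance approach), and `none`.
#'
#' @return character vector of length 4:
#'   `c("negative", "positive_self", "positive_social", "none")`.
#' @export
daily_messages <- function() c("negative", "positive_self", "positive_social", "none")

#' The weekly summary message catalog
#'
#' One fixed weekly reminder plus four achievement messages. Achievement
#' messages are rate-limited by the engine's cooldown (see
#' [weekly_summary()]).
#'
#' @return character vector of the five weekly message identifiers.
#' @export
weekly_messages <- function() {
  c("reminder", "maximal_increase", "significant_increase",
    "maximal_social", "significant_social")
}

#' Construct a weekly activity plan
#'
#' A personal prescription of walking, e.g. at least 2 hours per week divided
#' into 3 sessions. The three fields must be consistent:
#' `sessions_per_week * minutes_per_session` equals `weekly_target_minutes`
#' within 1 minute of rounding.
#'
#' @param weekly_target_minutes total prescribed walking minutes per week (> 0).
#' @param sessions_per_week number of walking sessions per week (positive integer).
#' @param minutes_per_session minutes per session; defaults to
#'   `round(weekly_target_minutes / sessions_per_week)`.
#' @return an object of class `activity_plan`.
#' @examples
#' activity_plan(120, 3)
#' @export
activity_plan <- function(weekly_target_minutes, sessions_per_week,
                          minutes_per_session = NULL) {
  if (!is.numeric(weekly_target_minutes) || weekly_target_minutes <= 0)
    stop("weekly_target_minutes must be positive")
  if (!is.numeric(sessions_per_week) || sessions_per_week <= 0 ||
      sessions_per_week != round(sessions_per_week))
    stop("sessions_per_week must be a positive integer")
  if (is.null(minutes_per_session))
    minutes_per_session <- round_half_up(weekly_target_minutes / sessions_per_week)
  if (minutes_per_session <= 0)
    stop("minutes_per_session must be positive")
  if (abs(sessions_per_week * minutes_per_session - weekly_target_minutes) > 1)
    stop("sessions_per_week * minutes_per_session must equal weekly_target_minutes (within 1 minute)")
  structure(
    list(weekly_target_minutes = as.numeric(weekly_target_minutes),
         sessions_per_week = as.integer(sessions_per_week),
         minutes_per_session = as.numeric(minutes_per_session)),
    class = "activity_plan")
}

#' Construct a patient record
#'
#' @param patient_id opaque identifier.
#' @param age age in years (> 0).
#' @param gender `"female"` or `"male"`.
#' @param plan an [activity_plan()].
#' @param arm `"treatment"` (daily adaptive messages) or `"control"`
#'   (fixed weekly reminder only); fixed for the patient's lifetime.
#' @param enrolled_on enrollment date.
#' @return an object of class `coach_patient`.
#' @export
patient <- function(patient_id, age, gender = c("female", "male"),
                    plan, arm = c("treatment", "control"),
                    enrolled_on = Sys.Date()) {
  gender <- match.arg(gender)
  arm <- match.arg(arm)
  if (!is.numeric(age) || age <= 0) stop("age must be positive")
  if (!inherits(plan, "activity_plan")) stop("plan must be an activity_plan")
  structure(
    list(patient_id = as.character(patient_id), age = as.numeric(age),
         gender = gender, plan = plan, arm = arm,
         enrolled_on = as.Date(enrolled_on)),
    class = "coach_patient")
}

#' Cumulative walking minutes in the week of a date
#'
#' Sums the recorded qualifying walking minutes over the days of the week
#' containing `date` (Monday-start convention, see [week_start()]), up to and
#' including `date`. Days not present in `history` contribute zero, so a
#' history that only extends through yesterday naturally yields the
#' morning-decision-time total.
#'
#' @param history data frame with columns `date` and `minutes`, sorted by
#'   date (one patient's activity records).
#' @param date the reference date.
#' @return total minutes (numeric scalar; 0 for an empty window).
#' @export
cumulative_week_minutes <- function(history, date) {
  date <- as.Date(date)
  if (is.null(history) || nrow(history) == 0) return(0)
  d <- as.Date(history$date)
  if (is.unsorted(d)) stop("history must be sorted by date")
  keep <- d >= week_start(date) & d <= date
  sum(history$minutes[keep])
}

#' Percent of the weekly activity goal achieved
#'
#' The integer "N%" substituted into the positive feedback messages:
#' `round(100 * week_minutes / weekly_target_minutes)`, half rounded up.
#' The value is not clamped above 100 (a patient past their goal sees
#' e.g. 125%) and is always >= 0.
#'
#' @param week_minutes minutes walked so far this week (>= 0).
#' @param plan an [activity_plan()].
#' @return integer percent >= 0.
#' @export
percent_of_goal <- function(week_minutes, plan) {
  if (!inherits(plan, "activity_plan")) stop("plan must be an activity_plan")
  if (any(week_minutes < 0)) stop("week_minutes must be >= 0")
  as.integer(round_half_up(100 * week_minutes / plan$weekly_target_minutes))
}

#' Expected fraction of the weekly goal completed by end of a day
#'
#' Under uniform accrual over the 7 days of the week, the fraction of the
#' weekly target a patient on track is expected to have completed by the end
#' of `date`: `day_index / 7` where Monday is day 1 and Sunday day 7. This
#' drives both the initial policy's positive/negative threshold and the
#' `fraction_vs_expected` feature of the learned policy.
#'
#' @param date calendar date (vectorized).
#' @return fraction in (0, 1].
#' @export
expected_fraction <- function(date) {
  weekday_index(date) / 7
}

.daily_templates <- list(
  negative = paste0("You need to exercise to reach your activity goals. ",
                    "Please remember to exercise tomorrow"),
  positive_self = paste0("You have so far achieved %d%% of your weekly activity goal. ",
                         "Your exercise level is in accordance with your plan. ",
                         "Keep up the good work"),
  positive_social = paste0("You have so far achieved %d%% of your weekly activity goal. ",
                           "You are exercising more than the average person in your group. ",
                           "Keep up the good work"),
  none = "")

.weekly_templates <- list(
  reminder = "Please remember to exercise this week to reach your activity goals.",
  maximal_increase = "Over the past week you increased your activity more than at any previous week.",
  significant_increase = "Over the past week you increased your activity more than most previous weeks.",
  maximal_social = "You won the first place! Last week you increased your activity more than any other participant in the experiment.",
  significant_social = "Last week you increased your activity more than most participants of the experiment.")

#' Render a daily feedback message as SMS text
#'
#' Pure template substitution: the two positive messages embed the integer
#' percent-of-goal, the negative message is fixed text, and `none` renders
#' as the empty string (no SMS is sent).
#'
#' @param message one of [daily_messages()].
#' @param percent integer percent of weekly goal (required, >= 0, for the two
#'   positive messages; ignored otherwise).
#' @return the message text (`""` for `none`).
#' @export
render_daily_message <- function(message, percent = NULL) {
  message <- match.arg(message, daily_messages())
  if (message %in% c("positive_self", "positive_social")) {
    if (is.null(percent) || is.na(percent) || percent < 0)
      stop("percent must be a nonnegative integer for positive messages")
    sprintf(.daily_templates[[message]], as.integer(percent))
  } else {
    .daily_templates[[message]]
  }
}

#' Render a weekly summary message as SMS text
#'
#' @param message one of [weekly_messages()].
#' @return the message text.
#' @export
render_weekly_message <- function(message) {
  message <- match.arg(message, weekly_messages())
  .weekly_templates[[message]]
}
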