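# Saving and loading trials as plain-text event logs (the on-disk formats
# the command-line tool exchanges).

#' Save / load a simulated trial as an event-log directory
#'
#' `save_trial` writes `cohort.csv`, `activity.csv`, `decisions.csv`,
#' `weekly.csv` and one JSON model snapshot per refit day under
#' `snapshots/`. `load_trial` reconstructs from such a directory everything
#' [evaluate_trial()] needs.
#'
#' @param trial a [simulate_trial()] result.
#' @param dir directory to write to / read from.
#' @param truth also write the latent simulator columns into `cohort.csv`
#'   (needed by evaluation oracles that compare against planted structure).
#' @return `load_trial`: a list of class `coach_trial`.
#' @export
save_trial <- function(trial, dir, truth = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(trial$cohort, file.path(dir, "cohort.csv"), truth = truth)
  write_activity_csv(trial$activity, file.path(dir, "activity.csv"))
  utils::write.csv(trial$decisions, file.path(dir, "decisions.csv"),
                   row.names = FALSE)
  if (!is.null(trial$weekly))
    utils::write.csv(trial$weekly, file.path(dir, "weekly.csv"),
                     row.names = FALSE)
  snapdir <- file.path(dir, "snapshots")
  dir.create(snapdir, showWarnings = FALSE)
  for (s in trial$snapshots)
    write_model_snapshot(s, file.path(snapdir,
                                      paste0("model_", s$fit_date, ".json")))
  invisible(dir)
}

#' @rdname save_trial
#' @export
load_trial <- function(dir) {
  cohort <- read_cohort_csv(file.path(dir, "cohort.csv"))
  activity <- read_activity_csv(file.path(dir, "activity.csv"))
  decisions <- utils::read.csv(file.path(dir, "decisions.csv"),
                               stringsAsFactors = FALSE)
  decisions$date <- as.Date(decisions$date)
  wfile <- file.path(dir, "weekly.csv")
  weekly <- if (file.exists(wfile))
    utils::read.csv(wfile, stringsAsFactors = FALSE) else NULL
  snaps <- sort(list.files(file.path(dir, "snapshots"), full.names = TRUE,
                           pattern = "\\.json$"))
  snapshots <- lapply(snaps, read_model_snapshot)
  dates <- sort(unique(activity$date))
  np <- nrow(cohort)
  idx <- cbind(match(activity$patient_id, cohort$patient_id),
               match(activity$date, dates))
  minutes <- matrix(NA_real_, np, length(dates))
  cadence <- matrix(NA_real_, np, length(dates))
  minutes[idx] <- activity$minutes
  cadence[idx] <- activity$cadence
  structure(
    list(cohort = cohort, decisions = decisions, activity = activity,
         snapshots = snapshots, weekly = weekly,
         minutes = minutes, cadence = cadence,
         days = length(dates), policy = NA_character_, seed = NA),
    class = "coach_trial")
}

#' Compute one morning's decisions from raw event logs
#'
#' A stateless convenience over the policy functions for running the engine
#' against externally supplied logs: applies the staleness guard and
#' selects a daily message for every treatment patient — via the learned
#' model when a snapshot is supplied, else via the initial policy.
#'
#' @param cohort cohort data frame ([read_cohort_csv()]).
#' @param activity activity data frame through yesterday
#'   ([read_activity_csv()]).
#' @param message_log prior decisions data frame (columns `patient_id`,
#'   `date`, `action`, `suppression_reason`), or `NULL`.
#' @param date the decision date.
#' @param model a `bandit_model` snapshot, or `NULL` for the initial policy.
#' @param config an [engine_config()].
#' @return decisions data frame (one row per patient).
#' @export
next_day_decisions <- function(cohort, activity, message_log, date,
                               model = NULL, config = engine_config()) {
  date <- as.Date(date)
  decision_time <- as.POSIXct(sprintf("%s %02d:00:00", date,
                                      config$decision_hour), tz = "UTC")
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    act <- activity[activity$patient_id == pid & activity$date < date, ,
                    drop = FALSE]
    act <- act[order(act$date), , drop = FALSE]
    if (cohort$arm[i] == "control") {
      out[[i]] <- data.frame(patient_id = pid, date = date,
                             phase = NA_character_, action = "none",
                             sent = FALSE, suppression_reason = "control_arm",
                             text = "", stringsAsFactors = FALSE)
      next
    }
    lt <- if (nrow(act)) max(act$last_transmission) else
      decision_time - 1e6
    if (staleness_guard(lt, decision_time, config$staleness_hours) ==
        "suppress") {
      out[[i]] <- data.frame(patient_id = pid, date = date,
                             phase = NA_character_, action = "none",
                             sent = FALSE, suppression_reason = "stale_data",
                             text = "", stringsAsFactors = FALSE)
      next
    }
    mlog <- if (!is.null(message_log))
      message_log[message_log$patient_id == pid &
                    message_log$suppression_reason == "none", , drop = FALSE]
    else NULL
    if (is.null(model)) {
      a <- choose_action_initial(expected_fraction(date),
                                 initial_policy_config(config$p_no_message))
      phase <- "initial"
    } else {
      x <- build_features(cohort[i, ], act[, c("date", "minutes")], mlog,
                          date, ds_cap = config$ds_cap)
      gains <- vapply(daily_messages(),
                      function(a) predict_gain(model, x, a), 0)
      a <- boltzmann_sample(gains, config$temperature)
      phase <- "learned"
    }
    pct <- percent_of_goal(cumulative_week_minutes(act, date),
                           activity_plan(cohort$weekly_target_minutes[i],
                                         cohort$sessions_per_week[i]))
    out[[i]] <- data.frame(patient_id = pid, date = date, phase = phase,
                           action = a, sent = a != "none",
                           suppression_reason = "none",
                           text = render_daily_message(a, pct),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
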