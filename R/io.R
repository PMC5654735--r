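# CSV interfaces: cohort and activity event logs (plain text, ISO-8601 dates).

#' Read / write a cohort CSV
#'
#' Columns: `patient_id, age, gender, arm, weekly_target_minutes,
#' sessions_per_week, enrolled_on`. Latent simulator columns (`cluster`,
#' `baseline_minutes`, ...), when present, are written only with
#' `truth = TRUE`.
#'
#' @param path file path.
#' @param cohort cohort data frame (as from [generate_cohort()]).
#' @param truth also write latent simulator columns.
#' @return `read_cohort_csv`: cohort data frame with `enrolled_on` as `Date`.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "gender", "arm",
            "weekly_target_minutes", "sessions_per_week", "enrolled_on")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort file missing columns: ", paste(miss, collapse = ", "))
  df$enrolled_on <- as.Date(df$enrolled_on)
  df
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path, truth = FALSE) {
  cols <- c("patient_id", "age", "gender", "arm",
            "weekly_target_minutes", "sessions_per_week", "enrolled_on")
  if (truth) cols <- union(cols, names(cohort))
  utils::write.csv(cohort[, intersect(cols, names(cohort))], path, row.names = FALSE)
  invisible(path)
}

#' Read / write an activity CSV
#'
#' One row per patient-day of measured walking: `patient_id, date, minutes,
#' cadence, last_transmission`. `minutes` counts only contiguous walking
#' bouts of 10 minutes or more; `cadence` is the mean steps per minute
#' during walking (0 on days without qualifying walking).
#'
#' @param path file path.
#' @param activity activity data frame.
#' @return `read_activity_csv`: data frame with `date` as `Date` and
#'   `last_transmission` as `POSIXct` (UTC).
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "date", "minutes", "cadence", "last_transmission")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("activity file missing columns: ", paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  df$last_transmission <- as.POSIXct(df$last_transmission, tz = "UTC")
  df
}

#' @rdname read_activity_csv
#' @export
write_activity_csv <- function(activity, path) {
  out <- activity
  out$last_transmission <- format(as.POSIXct(out$last_transmission, tz = "UTC"),
                                  "%Y-%m-%d %H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
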