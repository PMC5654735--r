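# Context features, Kesler action augmentation and interaction expansion.
#
# The per-patient-day context x has 10 numeric features in a fixed order:
#   minutes_last_day, cum_week_minutes, frac_goal, frac_vs_expected,
#   age, gender_female, ds_negative, ds_positive_self, ds_positive_social,
#   ds_none
# The Kesler construction appends a 4-long one-hot action block
# (a_negative, a_positive_self, a_positive_social, a_none), and the design
# row is the 14 base columns plus all pairwise products of distinct columns
# except products of two action indicators (structurally zero for a one-hot
# block): 14 + choose(14, 2) - choose(4, 2) = 99 columns.

#' Names of the context features
#'
#' @return character vector of the 10 feature names in design order.
#' @export
feature_names <- function() {
  c("minutes_last_day", "cum_week_minutes", "frac_goal", "frac_vs_expected",
    "age", "gender_female", paste0("ds_", daily_messages()))
}

# cached design layout: base column names, interaction pair indices,
# full design column names
design_info <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    base <- c(feature_names(), paste0("a_", daily_messages()))
    action_cols <- 11:14
    pairs <- utils::combn(14L, 2L)
    drop <- pairs[1, ] %in% action_cols & pairs[2, ] %in% action_cols
    pairs <- pairs[, !drop, drop = FALSE]
    nm <- c(base, paste0(base[pairs[1, ]], ":", base[pairs[2, ]]))
    cache <<- list(base = base, pairs = pairs, names = nm)
    cache
  }
})

#' Build the context feature vector for one patient-day
#'
#' Assembles the 10-feature context available at the morning decision time
#' of `date`: yesterday's qualifying walking minutes, cumulative minutes this
#' week, the fraction of the weekly goal achieved, that fraction relative to
#' the expected fraction for this point of the week, the demographics, and
#' the number of days since each of the four daily messages was last sent
#' (capped at `ds_cap` for messages never sent or sent long ago; the minimum
#' possible value is 1, the previous morning).
#'
#' @param patient a [patient()] (or any list with `age`, `gender` and
#'   either `plan` or `weekly_target_minutes`).
#' @param history the patient's activity data frame (`date`, `minutes`),
#'   sorted, typically extending through yesterday.
#' @param message_log data frame of prior sent decisions for this patient
#'   with columns `date` and `action` (rows where a daily action was taken).
#' @param date the decision date.
#' @param ds_cap cap for the days-since-message features (default 30).
#' @return named numeric vector of length 10 (see [feature_names()]).
#' @export
build_features <- function(patient, history, message_log, date, ds_cap = 30) {
  date <- as.Date(date)
  target <- if (!is.null(patient$plan)) patient$plan$weekly_target_minutes
            else patient$weekly_target_minutes
  if (is.null(target) || !is.numeric(target) || target <= 0)
    stop("patient has no valid activity plan")
  yesterday <- date - 1L
  ml <- 0
  if (!is.null(history) && nrow(history) > 0) {
    hit <- as.Date(history$date) == yesterday
    if (any(hit)) ml <- history$minutes[hit][1]
  }
  cwm <- cumulative_week_minutes(history, date)
  fg <- cwm / target
  fve <- fg / expected_fraction(date)
  ds <- rep(ds_cap, 4)
  names(ds) <- daily_messages()
  if (!is.null(message_log) && nrow(message_log) > 0) {
    for (j in daily_messages()) {
      sent <- as.Date(message_log$date[message_log$action == j])
      sent <- sent[sent < date]
      if (length(sent)) ds[j] <- min(as.integer(date - max(sent)), ds_cap)
    }
  }
  x <- c(ml, cwm, fg, fve, patient$age,
         as.numeric(patient$gender == "female"), ds)
  names(x) <- feature_names()
  x
}

#' Augment a context with a one-hot action block (Kesler construction)
#'
#' @param x context feature vector (length 10, order of [feature_names()]).
#' @param action one of [daily_messages()].
#' @return numeric vector of length 14: the features followed by the
#'   one-hot action indicators, exactly one of which is 1.
#' @export
kesler_augment <- function(x, action) {
  action <- match.arg(action, daily_messages())
  if (length(x) != 10) stop("x must have the 10 context features")
  a <- as.numeric(daily_messages() == action)
  out <- c(as.numeric(x), a)
  names(out) <- design_info()$base
  out
}

#' Expand an augmented row into the interaction design row
#'
#' Main effects plus all pairwise products of distinct columns, excluding
#' products of two action indicators (structurally zero for a one-hot
#' block). Column order is fixed and deterministic: the 14 base columns in
#' order, then pairs in `combn` order.
#'
#' @param x augmented row of length 14 (from [kesler_augment()]), or a
#'   matrix with 14 columns (one augmented row per line).
#' @return design row of length 99 (or matrix with 99 named columns).
#' @export
expand_interactions <- function(x) {
  di <- design_info()
  if (is.matrix(x)) {
    if (ncol(x) != 14) stop("x must have 14 columns")
    out <- cbind(x, x[, di$pairs[1, ], drop = FALSE] * x[, di$pairs[2, ], drop = FALSE])
    colnames(out) <- di$names
    out
  } else {
    if (length(x) != 14) stop("x must have length 14")
    out <- c(x, x[di$pairs[1, ]] * x[di$pairs[2, ]])
    names(out) <- di$names
    out
  }
}
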