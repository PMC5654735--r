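# The predetermined stochastic policy used during the initial phase.
#
# Scheme: with probability p_no_message send nothing; otherwise draw
# u ~ U(0,1) and send the negative message if u is strictly larger than the
# expected fraction of weekly activity for that day, else one of the two
# positive messages with equal probability. The tie u == f goes to a
# positive message ("larger than" is strict).

#' Initial-policy configuration
#'
#' @param p_no_message probability that no message is sent on a day
#'   (default 0.20).
#' @return a list of class `initial_policy_config`.
#' @export
initial_policy_config <- function(p_no_message = 0.2) {
  if (!is.numeric(p_no_message) || p_no_message < 0 || p_no_message > 1)
    stop("p_no_message must be in [0, 1]")
  structure(list(p_no_message = p_no_message), class = "initial_policy_config")
}

#' Analytic action distribution of the initial policy
#'
#' For a day whose expected fraction of weekly activity is `f`, the initial
#' policy selects: no message with probability `p`; otherwise negative with
#' probability `1 - f` (the uniform draw exceeded the expected fraction) or
#' one of the two positive messages with probability `f / 2` each.
#'
#' @param f expected fraction of weekly activity for the day, in \[0, 1\].
#' @param config an [initial_policy_config()].
#' @return named probability vector over [daily_messages()], summing to 1.
#' @examples
#' action_distribution(0.5)
#' @export
action_distribution <- function(f, config = initial_policy_config()) {
  if (!is.numeric(f) || length(f) != 1 || is.na(f) || f < 0 || f > 1)
    stop("f must be a single number in [0, 1]")
  p <- config$p_no_message
  c(negative = (1 - p) * (1 - f),
    positive_self = (1 - p) * f / 2,
    positive_social = (1 - p) * f / 2,
    none = p)
}

#' Sample one day's action from the initial policy
#'
#' Draws in the policy's narrative order: first the Bernoulli no-message
#' decision, then the uniform threshold draw against `f`, then the
#' equal-probability choice between the two positive messages. Reproducible
#' under `set.seed()`.
#'
#' @inheritParams action_distribution
#' @return one of [daily_messages()].
#' @export
choose_action_initial <- function(f, config = initial_policy_config()) {
  if (!is.numeric(f) || any(is.na(f)) || any(f < 0) || any(f > 1))
    stop("f must be in [0, 1]")
  n <- length(f)
  out <- character(n)
  no_msg <- stats::runif(n) < config$p_no_message
  u <- stats::runif(n)
  pos_self <- stats::runif(n) < 0.5
  out[no_msg] <- "none"
  out[!no_msg & u > f] <- "negative"
  rest <- !no_msg & u <= f
  out[rest & pos_self] <- "positive_self"
  out[rest & !pos_self] <- "positive_social"
  out
}
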