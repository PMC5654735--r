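# fixtures built in code: toy decision logs and naive oracles

toy_decisions <- function(actions, rewards, phase = "initial",
                          patient_id = "P01",
                          dates = as.Date("2016-01-04") + seq_along(actions) - 1) {
  data.frame(patient_id = patient_id, date = dates,
             day = as.integer(dates - min(dates)) + 1L,
             phase = phase, action = actions, sent = actions != "none",
             suppression_reason = "none", text = "",
             reward = rewards, stringsAsFactors = FALSE)
}

# independent double-loop oracle for the interaction expansion
naive_expand <- function(x) {
  stopifnot(length(x) == 14)
  out <- as.numeric(x)
  nm <- names(x)
  onm <- nm
  for (i in 1:13) for (j in (i + 1):14) {
    if (i >= 11 && j >= 11) next  # two action indicators
    out <- c(out, x[i] * x[j])
    onm <- c(onm, paste0(nm[i], ":", nm[j]))
  }
  names(out) <- onm
  out
}

# a minimal hand-built bandit_model with chosen coefficients
manual_model <- function(coef = numeric(99), intercept = 1) {
  manifest <- names(expand_interactions(kesler_augment(rep(0, 10), "none")))
  structure(list(intercept = intercept,
                 coef = stats::setNames(rep_len(coef, 99), manifest),
                 manifest = manifest, n = NA, p = 99, r2 = NA, adj_r2 = NA,
                 sigma2 = NA_real_, vcov_unscaled = NULL, lambda = 0,
                 reward_cap = 10, fit_date = NA),
            class = "bandit_model")
}

random_context <- function() {
  x <- c(runif(1, 0, 120), runif(1, 0, 300), runif(1, 0, 2), runif(1, 0, 3),
         runif(1, 35, 75), rbinom(1, 1, 0.5), sample(1:30, 4, replace = TRUE))
  names(x) <- feature_names()
  x
}
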