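Package: adaptivecoach
Title: Contextual-Bandit SMS Coaching for Physical Activity in Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a daily SMS feedback loop that encourages physical
    activity in sedentary type 2 diabetes patients: an initial stochastic
    messaging policy, a contextual-bandit learned policy (Kesler action
    augmentation, interaction-expanded ridge-stabilized least squares refit
    daily, Boltzmann exploration), a daily intervention engine with staleness
    guards and weekly achievement summaries, a synthetic patient cohort
    simulator with cluster-structured treatment response and behaviour
    shocks, and the evaluation analyses (per-message effectiveness,
    sequential effects, k-means response clustering, fit-weighted activity
    and cadence slopes, model stability traces, and relative HbA1c
    reduction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
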