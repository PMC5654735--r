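---
title: "Methods: a contextual-bandit SMS coach and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a contextual-bandit SMS coach and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptivecoach)
```

## The decision loop

Every morning, for every treatment-arm patient, the engine chooses one of
four daily messages — negative, positive-self, positive-social, or none —
and assesses yesterday's choice once the new day's activity data arrive.
Two policies share this loop.

**Initial policy** (first 90 days). With probability 0.2 no message is
sent. Otherwise a uniform draw $u$ is compared against the expected
fraction $f$ of the weekly goal for that day; $u > f$ (strictly) sends the
negative message, else one of the two positive messages with equal
probability. The tie $u = f$ goes to a positive message — a measure-zero
event, but the convention is fixed for reproducibility. We treat the 20%
no-message days as i.i.d. Bernoulli per patient-day rather than scheduled.

**Learned policy.** The context is a 10-feature vector $x_{i,t}$: minutes
of activity the previous day, cumulative minutes this week, fraction of the
weekly goal, that fraction relative to the expected fraction, age, a female
indicator, and the days since each of the four messages was last sent. The
action enters by the Kesler construction — a one-hot block appended to
$x_{i,t}$ — and the design is expanded to all pairwise interactions of the
14 columns, excluding products of two action indicators (structurally zero),
for $14 + \binom{14}{2} - \binom{4}{2} = 99$ columns. A linear model refit
every morning on all accumulated examples predicts the reward

$$y_{i,t} = \frac{m_{i,d} + \varepsilon}{m_{i,d-1} + \varepsilon},
\qquad \varepsilon = 1\ \text{minute},$$

the day-over-day activity ratio for the message day. The four predicted
gains are turned into a selection distribution by Boltzmann sampling at
fixed temperature $T = 5$, never adapted.

*Reward timing.* We resolve an ambiguity in the loop's narrative by fixing:
a decision sent on the morning of day $d$ influences day-$d$ activity; its
reward compares day $d$ with day $d-1$ and is finalized the following
morning, when day-$d$ data have arrived. If those data are stale the
example is dropped — no training pair is emitted for the gap.

*Why $\varepsilon = 1$ and winsorization.* The raw ratio is undefined on
zero-activity days; one minute of regularization keeps it defined while
changing nothing on equal days. Ratios remain heavy-tailed (a 30-minute
walk after a zero day gives $y = 31$), so rewards are winsorized at 10
before fitting to bound leverage; both values are configuration
(`engine_config(epsilon=, reward_cap=)`, raw mode via `epsilon = 0`).

## The regression and its numerics

With an intercept, the one-hot block, the feature main effects, and all
action-by-feature products, the design is *exactly* rank-deficient: the
four action indicators sum to the intercept column, and each feature's four
action interactions sum to that feature. We keep the explicit fourth
indicator (the action space genuinely has four members) and stabilize the
normal equations with a ridge penalty, $\lambda = 10^{-6}$, applied on the
scale of each column's root-mean-square and proportional to $n$, so its
effect is uniform across raw feature scales and vanishes relative to the
data as $n$ grows. The system is solved in the RMS-scaled basis (the raw
interaction columns span ~12 orders of magnitude) with one step of
iterative refinement, since forming normal equations squares the condition
number. The intercept is never penalized.

A consequence worth stating: individual action main-effect coefficients are
not identified — only differences between actions at a context are. The
package therefore exposes `action_contrast()` (estimate and standard error
of action-vs-reference at a context) and all tests of "coefficient
recovery" check fitted values and identified contrasts, not raw aliased
coefficients. Predictions, and hence the policy, are unaffected by the
aliasing.

The learned phase activates only after the 90-day initial phase *and* at
least 200 finalized examples (`min_examples`); below that the fit signals
insufficient data and the engine stays on the initial policy. Days-since-
message features are capped at 30 so never-sent messages give a bounded
value; the minimum is 1 (sent the previous morning). Gender is a single
indicator, age in years unscaled; feature standardization is intentionally
off so coefficients stay interpretable (the internal solver scales
regardless).

Other fixed conventions: weeks start on Monday; expected accrual is uniform
over the 7 days (the plan prescribes session counts, not a schedule);
percent-of-goal rounds half up and is not clamped above 100; the staleness
boundary is inclusive (a gap of exactly 12 hours suppresses). Weekly
achievements require at least one *previous* weekly increase (a maximum
over an empty history does not count), use strict comparisons, compare
social variants against the other participants' increases that week, and
respect a 21-day cooldown with precedence maximal-increase >
maximal-social > significant-increase > significant-social.

## What the simulator emulates

`simulator_config()` encodes the emulated study conditions: 20 treatment
and 7 control patients; weekly plans from a truncated normal (mean 139, SD
62, minimum 30 min/week) split into 3 sessions; three latent response
clusters mixed 4:9:5 with female shares 50% / 67% / 20%; ages ~N(57, 7²)
truncated to [35, 75] (the clusters' mean ages differ little by design).
Daily behaviour is multiplicative-lognormal:

$$m_{i,d} = \text{baseline}_i \cdot H_{i,d-1} \cdot
\text{mult}_{c(i)}(a_d) \cdot \text{seq}(a_{d-1}, a_d) \cdot
\text{shock}_d \cdot e^{\sigma Z},\qquad \sigma = 0.25,$$

rounded to whole minutes with totals under 10 recorded as zero (only
qualifying bouts count). The cluster multipliers default to
(0.75, 0.80, 0.80, 1) for cluster 1 — every message hurts — (0.90, 1.05,
1.10, 1) for the weak cluster 2, and (0.70, 1.60, 2.00, 1) for the strong
responders of cluster 3, over (negative, positive-self, positive-social,
none). Baselines scale with cluster (0.9, 1.2, 1.6 × plan/7), so responder
status is partially visible to the learner through activity levels as well
as gender. The sequence table boosts negative→positive-self (×1.2) and
damps repeated positive-social (×0.85). A week-long shock (severity 0.6)
hits at day 150 — about day 60 of the learned policy's operation — where it
is visible as a jump in the coefficient-stability trace. Transmission gaps
of 12–48 h occur on 5% of patient-days to exercise the staleness guard.

These multiplier values are free configuration: they were chosen once, at
the start of development, to produce clearly separated clusters (the test
suite's planted-effect recovery and clustering checks run at exactly these
defaults), after a first pass with lower cluster-1 baselines proved
degenerate — patients fell below the 10-minute bout threshold on most
message days and the resulting $(m+1)/1$ reward spikes drowned every
planted signal. They are a caricature of heterogeneous response, not an
estimate of any real effect size.

**Adherence drift.** The latent habit $H$ makes a fraction
$\kappa = 0.10$ of each day's planted message effect persist on the log
scale, relaxing toward baseline at rate 0.05/day and clamped to
[0.5, 2.5]×baseline. Without it, message effects fully mean-revert
overnight and *no* policy can change a patient's activity trajectory; with
it, systematically helpful messages compound, treatment-arm activity and
cadence slopes come out positive while the control arm drifts down, and
the evaluation's slope analyses have something real to measure. Setting
$\kappa = 0$ restores a stationary world and is the negative-control
configuration.

**A structural note on ratio rewards.** Day-over-day ratio rewards
telescope: $\sum_d \log y_d = \log m_D - \log m_0$, so the long-run mean
log-reward measures only net growth, not per-day policy quality, and in
levels the residual policy-sensitive term is a dispersion bonus
($E[\text{mult}]\,E[1/\text{mult}] > 1$) that *favors more random
policies*, amplified by the winsorization cap's one-sided upside on
zero-day spikes. A myopic bandit at $T = 5$ therefore cannot be expected to
dominate a uniform-random policy on mean ratio reward in head-to-head
simulation — its benefit appears in activity levels and slopes (through
the adherence drift), in its preferential selection of each subgroup's
planted-best message, and in per-context predicted gains. The test suite
measures the head-to-head mean-reward comparison anyway and treats its
outcome honestly; the comparison that separates policies decisively is the
activity trajectory, not the telescoping ratio.

What the generator does *not* emulate: step-level accelerometer noise,
weekly schedules (sessions vs daily accrual), seasonal and weekday
structure, dropout, measurement-device changes, or any physiological
glucose dynamics — the optional HbA1c channel is a linear toy
(−0.05 %-points per 1000 minutes walked) for demonstrating the relative-
reduction computation, not a clinical claim. Passing tests on this
simulator show the algorithms are implemented correctly and can recover
planted structure of realistic magnitude; they say nothing about effect
sizes in real cohorts.

## Evaluation conventions

Per-message effectiveness weights per-message mean rewards by empirical
selection frequencies, per policy phase; messages never sent are reported
missing, not zero. Sequential effects use consecutive same-patient days
only (the table is descriptive — pairs are policy-chosen, not randomized).
Response clustering uses `stats::kmeans` with 50 restarts on per-patient
mean-response vectors (patients with ≥ 2 distinct received messages; cells
for never-received messages imputed with the patient's own mean; rewards
winsorized as in fitting), and relabels clusters by ascending centroid
mean so "cluster 1" is always the most negatively reacting group. Slopes
are OLS per patient with the fit's $R^2$ as group-averaging weight ("fit of
the linear function" is not otherwise defined; $R^2$ is the natural
choice); cadence slopes use weekly means excluding non-walking weeks, since
cadence is undefined without walking. The stability trace is
$\sum_j \bigl|\,|\beta_j(d)| - |\beta_j(d-1)|\,\bigr|$ including the
intercept — read literally, a sign flip with unchanged magnitude
contributes zero.

## Problem sizes

The default closed loop is 27 patients × 180 days (90 initial + 90
learned), ≈ 3,300 finalized training examples and 90 daily refits of the
99-column model, which runs in a few seconds. The test suite's heaviest
checks are 20-seed replicate studies of the full loop (paired
adaptive-vs-uniform comparisons under common random numbers: environment
noise is pre-drawn per patient-day from the seed, so two policies face
identical patients and days). Parameter-recovery checks use n = 2,000
simulated examples at noise SD 0.2; the adjusted-$R^2$ consistency check
uses n = 5,000.

## Known limitations

One shared model across patients (no per-subgroup plurality); myopic
one-step credit assignment (deliberately a contextual bandit, not
Q-learning); the identifiability caveat above; calendar effects and
real-world nonstationarity absent from the simulator; and the weekly
summary logic assumes trials start on a Monday (the default) so that
completed weeks align with plan weeks.
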