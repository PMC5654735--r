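# adaptivecoach

Personalized SMS coaching for physical activity in type 2 diabetes,
implemented as a contextual bandit — together with a synthetic patient
simulator and the evaluation analyses, so the whole closed loop can be
exercised and tested without any real patient data.

## The problem and the method

Sedentary patients with type 2 diabetes receive a personal weekly walking
plan (e.g. 120 minutes divided into 3 sessions). A smartphone app measures
qualifying walking (contiguous bouts of ≥ 10 minutes) and uploads it to a
server. Each morning the system chooses one of four daily SMS messages for
every treatment-arm patient:

1. **negative** — "You need to exercise to reach your activity goals…"
2. **positive-self** — "You have so far achieved N% of your weekly activity goal…"
3. **positive-social** — "…You are exercising more than the average person in your group…"
4. **none** — no SMS.

For an initial period of 90 days a predetermined stochastic policy is used:
no message on 20% of days; otherwise a uniform draw *u* against the expected
fraction *f* of the weekly goal (day-of-week / 7) sends the negative message
when *u* > *f*, else one of the two positive messages with equal
probability.

Afterwards a **learned policy** takes over. Each patient-day is a context

x = (minutes last day, cumulative week minutes, fraction of goal,
fraction vs expected, age, gender, days since each of the 4 messages),

augmented with a one-hot action block *A* (Kesler construction) and expanded
to all pairwise interactions (99 design columns). A ridge-stabilized linear
regression, refit every morning on all collected examples, predicts the
reward

y = (minutes on the message day + ε) / (minutes on the previous day + ε),  ε = 1,

and the message is sampled by Boltzmann exploration over the four predicted
gains,

P(a) ∝ exp(ŷ(x, a) / T),  T = 5,

so that likely-effective messages are favored while every message keeps a
probability above 10%. Messages are suppressed when no device data arrived
for ≥ 12 hours. Weekly summaries add achievement messages (maximal /
significant increase, personal or social) at most once per 3 weeks;
control-arm patients only ever receive a fixed weekly reminder.

The **simulator** emulates a 27-patient cohort (20 treatment, 7 control)
with plans ~N(139, 62) min/week, three response clusters mixed 4:9:5
(cluster 1 reacts negatively to any message, cluster 2 weakly, cluster 3
strongly with positive-social best), gender composition per cluster, message
sequence effects, transmission gaps, week-long behaviour shocks, and an
adherence-drift channel by which a fraction of each day's message effect
persists. The **evaluation** module implements the analysis battery:
per-message effectiveness, sequential 4×4 effects, k-means response
clustering (k = 3, labels ordered so cluster 1 is most negative),
fit-weighted (R²) per-patient activity and cadence slopes, day-to-day model
stability and adjusted-R² traces, and relative HbA1c reduction
(HbA1c[0] − HbA1c[t]) / HbA1c[0].

## Worked example

```r
library(adaptivecoach)
tr <- simulate_trial(days = 180, seed = 1)   # 90 initial + 90 learned days
tr
#> coach_trial: 27 patients, 180 days, policy = adaptive , seed = 1
#>   decisions: 4860  examples: 3273 finalized

rep <- evaluate_trial(tr)
subset(rep$effectiveness, phase == "learned")
#>     phase          action mean_reward   n  freq effectiveness
#> 5 learned        negative       0.995 386 0.239          1.49
#> 6 learned   positive_self       1.809 395 0.245          1.49
#> 7 learned positive_social       1.537 461 0.286          1.49
#> 8 learned            none       1.608 370 0.230          1.49

round(rep$activity_slopes, 4)   # fit-weighted slope of fraction-of-goal/day
#> treatment   control
#>    0.0053   -0.0014
round(rep$cadence_slopes, 4)    # steps/minute per week
#> treatment   control
#>    0.1858   -0.0610
tail(rep$trace$adj_r2, 1)       # predictability of next-day behaviour
#> [1] 0.301
```

`mean_reward` is the average day-over-day activity ratio following each
message (> 1 = activity increased), `freq` the learned policy's empirical
selection rate — positive-social is selected most (28.6%), every message
stays well above 10%. The treatment arm's activity and walking-cadence
slopes are positive while the control arm declines, and the refit model's
adjusted R² stabilizes around 0.3: much of day-to-day behaviour is
predictable from the context features.

A command-line front end is installed with the package
(`system.file("scripts", "adaptive-coach", package = "adaptivecoach")`):

```sh
adaptive-coach simulate --days 180 --seed 1 --out trial/ --truth
adaptive-coach evaluate --log trial/ --report report.json
adaptive-coach run-policy --cohort trial/cohort.csv \
    --activity trial/activity.csv --state trial/ --date 2016-07-02
```

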