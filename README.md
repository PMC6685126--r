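# lonelysense

Detecting loneliness in college students from passively sensed smartphone
and wearable data.

Loneliness is typically assessed with the 20-item revised UCLA scale
(items rated 1–4, nine reverse scored, totals 20–80, dichotomized at 40:
above 40 = high loneliness, HL; otherwise low, LL). This package
implements the passive-sensing counterpart end to end:

1. **Synthetic cohort generator** — AWARE-style smartphone streams
   (location and Bluetooth at 1 sample/10 min, screen events, call/SMS
   logs with contact groups, audio-class inferences) plus Fitbit-style
   steps (1/5 min) and sleep states (1/min) over a study calendar, with
   *planted*, effect-size-scaled behavioral differences between high- and
   low-loneliness participants (weekend-evening off-campus time,
   weekday-evening social-event time, activity level, night-time phone
   use). Raw data of this kind are not publicly shareable, so the
   generator is the test bed for every downstream stage.
2. **Survey scoring** — UCLA-20 totals, LL/HL levels, change categories
   (decreased / increased / unchanged loneliness) and cohort summaries.
3. **Feature extraction** — per time segment (epoch × day-of-week filter ×
   granularity; the default axes give 5×3×3 = 45 segment types), seven
   feature sets: location (speeds, DBSCAN significant places, radius of
   gyration, location entropy, Lomb–Scargle circadian regularity, home),
   campus map (8 place categories, bouts, study/social duration), steps
   (active/sedentary bouts), sleep (weak/strong efficiency, bout
   statistics), screen (interaction/unlocked sessions, hourly first/last
   event indicators), calls/SMS (direction × audience), and Bluetooth
   (self/related/others device classification by score clustering).
4. **Detection pipeline** — nested randomized logistic regression (NRLR)
   feature selection and logistic-regression-vs-gradient-boosting model
   selection inside leave-one-subject-out cross-validation, AdaBoost
   fusion of the per-set detection probabilities, a 120-combination
   feature-set ablation, and metrics including the Matthews correlation
   coefficient.
5. **Association mining** — equal-frequency discretization and Apriori
   with a restricted consequent vocabulary, for question-level rules
   (`Q14>=3 → level=HL`) with the raise-support-until-empty search and for
   behavior-level rules over classifier-selected features (support 10%,
   confidence 90%).

## Worked example

```r
library(lonelysense)

# a small synthetic cohort: 8 participants, 2 study weeks
cal <- study_calendar("2017-01-18", n_weeks = 2L, half_split_week = 1L)
coh <- generate_cohort(8, effect_size = 1, calendar = cal, seed = 42)

# survey scoring: the response with post-reversal value 2 everywhere
raw <- rep(2L, 20); raw[ucla_reverse_items()] <- 3L
score_ucla(raw)
#> [1] 40
categorize_level(score_ucla(raw))
#> [1] "LL"

# planted truth of the simulated cohort
coh$truth[1:3, .(participant_id, pre_total, post_total, post_level, change)]
#>    participant_id pre_total post_total post_level change
#>            <char>     <int>      <int>     <char> <char>
#> 1:           P001        38         37         LL     UL
#> 2:           P002        69         69         HL     UL
#> 3:           P003        49         38         LL     DL

# sleep features on a constructed stream: 300 asleep / 30 restless /
# 20 awake minutes
sl <- data.frame(
  timestamp = as.POSIXct("2017-01-18", tz = "UTC") + 60 * (0:349),
  state = rep(c("asleep", "restless", "awake"), c(300, 30, 20)))
round(sleep_features(sl)[c("weak_sleep_efficiency", "strong_sleep_efficiency")], 4)
#>   weak_sleep_efficiency strong_sleep_efficiency
#>                  0.9429                  0.8571
```

The `analysis/` directory chains the full study workflow at desk scale
(32 participants, 6 weeks); each script prints what it found and writes
its tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # streams, surveys, campus GeoJSON
Rscript analysis/02_score_surveys.R     # outcomes, summary, change bands
Rscript analysis/03_extract_features.R  # 7 per-set feature matrices
Rscript analysis/04_classify.R          # LOSO + ensemble + ablation
Rscript analysis/05_mine_rules.R        # question- and behavior-level rules
```

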