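---
title: "Passive sensing of loneliness: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive sensing of loneliness: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Loneliness in college students is usually measured by self-report — here
the 20-item revised UCLA scale, each item rated 1 (never) to 4 (always),
nine items reverse scored, totals in 20–80, dichotomized at 40 (a
participant answering "rarely" throughout scores exactly 40, so totals
above 40 indicate at least sometimes feeling lonely). `lonelysense`
implements a full passive-sensing counterpart: behavioral features are
extracted from smartphone and wearable streams collected over a semester,
a per-sensor ensemble classifier detects the post-semester loneliness
level (LL/HL) and its change category (decreased DL / increased IL /
unchanged UL), and Apriori association mining describes which behavior
combinations accompany loneliness.

Because raw data of this kind cannot be shared, the package is exercised
end to end on a synthetic cohort generator whose planted
behavior–loneliness links play the role of ground truth.

# Time segmentation

Every feature is computed within a *time segment*: an epoch of the day
(all day; night 12 am–6 am; morning 6 am–12 pm; afternoon 12 pm–6 pm;
evening 6 pm–12 am), a day-of-week filter (all days; weekdays Mon–Fri;
weekends Sat–Sun) and an aggregation granularity (whole semester; the two
unequal semester halves, split after week 6 of 16 by default; single
weeks). The default axes give 5 × 3 × 3 = 45 segment types.

Numerical conventions: epochs are half-open clock intervals, so midnight
belongs to the night epoch and the four named epochs partition the day
exactly (a property the tests assert on random streams). Point samples
are attributed to a segment by their timestamp. Duration events — calls,
screen sessions, place bouts — are *clipped* to each window they overlap,
so total time is conserved across the epoch partition; the alternative
(attributing an event wholly to the window of its start) would leak time
across midnight boundaries, which matters for night features.

# Feature families

* **Location** (`compute_speeds`, `cluster_static_points`,
  `mobility_features`): consecutive-sample speeds by haversine distance,
  the 1 km/h moving/static rule, DBSCAN significant places both *global*
  (whole study) and *local* (per window), location variance, total
  distance, radius of gyration about the time-weighted centroid, time at
  the top-3 places, time share at noise locations, stay-length statistics,
  location entropy −Σ pᵢ ln pᵢ over non-noise time shares with its
  ln(k)-normalized variant (defined 0 for k ≤ 1), Lomb–Scargle circadian
  movement regularity at the 24-h period, and time at home within 10 m and
  100 m of the inferred home (the center of the most frequented night-time
  cluster).
* **Campus map** (`assign_campus_category`, `campus_features`): each
  sample is labeled with one of 8 categories — six labeled polygon types
  (two social-event houses, student apartments, residential halls,
  athletic facilities, green spaces), *academic* for on-campus space
  outside any labeled polygon, and *off campus*. Per category: minutes,
  share, bouts, bouts of ≥10/20/30 min, bout-length statistics, plus
  category transitions, and the two multimodal durations: *study duration*
  (≥30 min continuously academic, every overlapping 5-min step interval
  below 10 steps, no phone interaction session overlapping) and *social
  duration* (≥20 min in residential buildings or green spaces with ≥80%
  of audio inferences voice or noise).
* **Steps** (`segment_step_bouts`, `step_features`): totals, the maximum
  5-min count, active/sedentary bouts and their statistics. A 5-min
  interval is sedentary below 10 steps; the boundary case (exactly 10) is
  treated as active so that a single threshold separates the two kinds,
  and the threshold is a config key. Grid gaps longer than one interval
  end the current bout: unknown activity should not extend a bout.
* **Sleep** (`sleep_features`): counts of asleep/restless/awake minutes,
  weak efficiency (asleep+restless over asleep+restless+awake) and strong
  efficiency (asleep over the same denominator), per-state bout statistics
  and the clock hours of the longest/shortest bouts. Unknown samples are
  excluded from all denominators and split bouts.
* **Screen** (`screen_sessions`, `screen_features`): interaction sessions
  run unlock → first off/lock, unlocked sessions unlock → lock; a trailing
  unlock is truncated at the window end. Features: unlocks per minute,
  total interaction/unlocked time, first/last event hours, session-length
  statistics, and 24 per-hour indicators of the first/last unlock, on and
  lock events (share of observed days).
* **Calls/SMS** (`call_sms_features`): counts (and durations for calls)
  per direction × audience (everyone, family, friends on/off campus), and
  distinct-correspondent counts. SMS mirror calls without durations.
* **Bluetooth** (`classify_bluetooth_devices`, `bluetooth_features`):
  devices are classified once per study into self/related/others by the
  score-and-cluster procedure — z-normalized number-of-days plus average
  daily frequency, K-means at K = 2 and K = 3, the smaller total
  within-cluster SSE wins (K = 2 only on a strict win), top cluster =
  self. Scan features (unique devices, most/least frequent device, scan
  count statistics) are computed for all devices, self∪related, and
  others.

Feature names carry the segment in bracket notation, e.g.
`off_campus_min [evening, weekends, semester]`, and the bracket suffix
defines the column groups used by the nested feature selection.

# Missing data

Per feature set: a feature missing for more than 30 participants is
dropped (the same feature in different segments is treated
independently); a participant missing at least 20% of the remaining
features is dropped; surviving missing cells are imputed with −1, which
is distinguishable because every real feature value is non-negative. The
column threshold is an absolute count calibrated to a 160-person cohort
(~19%); analyses run at reduced cohort sizes scale it proportionally
(`round(30/160 * n)`), otherwise a stream that is structurally empty in a
segment (e.g. sleep in the evening epoch) could never be dropped and
would instead eliminate every participant.

# Detection pipeline

All supervised steps run inside leave-one-subject-out cross-validation;
feature selection, model fitting and every standardization statistic see
only the n−1 training rows (asserted in the tests by flipping the
held-out label and checking the fold is bit-identical).

**NRLR.** Nested randomized logistic regression: stage 1 runs stability
selection — L1-penalized logistic fits on random 75% row subsamples with
per-feature penalty weights drawn uniformly from [0.5, 1] — separately
within each time-segment column group, keeping features selected in at
least 25% of subsamples; stage 2 pools all stage-1 survivors and repeats
the procedure once. Within each randomized fit the coefficient path is
read at the most regularized solution with about √p active features, a
sparsity anchor that keeps selection frequencies comparable across groups
of different width. The subsample count (200), subsample fraction,
threshold and weakness are config keys; the 3-class change task uses
one-vs-rest passes combined by the maximum frequency.

**Per-set models.** For each feature set, ridge-regularized logistic
regression and gradient boosting (xgboost, depth 3) are both fit on the
selected features; an inner stratified 5-fold CV picks the more accurate
one, ties resolving to logistic regression as the simpler model. An empty
selection falls back to the training majority prior. Held-out class
probabilities from the chosen model populate the probability table.

**Ensemble.** Detection probabilities are concatenated across feature
sets — one class per set for the binary level task, all three classes per
set for change — and AdaBoost (SAMME) with gradient-boosting base
estimators is trained and evaluated leave-one-out on these meta-features.
Participants missing from any included set are excluded (row
intersection); imputing their probabilities at the class prior is a
config alternative. The ablation study reruns the ensemble for every
subset of ≥2 feature sets: 7 sets give C(7,2)+…+C(7,7) = 120
combinations.

**Metrics.** Accuracy, per-class precision/recall/F1 with macro averages,
the majority-class baseline, and the Matthews correlation coefficient in
its covariance (multiclass) form, which reduces to the familiar binary
formula.

# Association mining

Features are discretized into low/moderate/high by equal-frequency
binning with nearest-rank edges; ties go to the lower bin, and a
duplicate edge advances to the next distinct value so every label stays
reachable (columns with fewer than three distinct values are excluded).
Discretization happens on observed values before imputation. Apriori is
level-wise candidate generation with the downward-closure prune, checked
in the tests against exhaustive enumeration; rules are restricted to a
declared consequent vocabulary (loneliness level, change category or a
single-question response level), so behavior→behavior rules are never
emitted. The question-level analysis encodes items as `Qk>=3`
("sometimes or always") and supports the iterative raise-support search:
starting from 10%, the support floor rises in 1-point steps until no rule
survives, and the largest support that still yields a rule is reported
(with the default thresholds, 38% support at 90% confidence is a typical stopping point). The behavior-level
analysis mines the features selected in more than half of the LOSO folds
at support 10% and confidence 90%.

# The synthetic cohort generator

`generate_cohort()` draws a latent loneliness per participant from
Beta(1.35, 1.55) — calibrated once so that with the survey response model
(scored value = round(1 + 3·latent + N(0, 0.55)) clamped to 1..4) roughly
60% of participants fall above the 40-point cutoff, the prevalence band
typical of college cohorts on this instrument — and simulates a
daily place schedule (home nights, weekday classes in academic buildings,
lunch, optional athletics, evening options) from which all eight streams
derive at their native cadences (location/Bluetooth 1 per 10 min, steps 1
per 5 min, sleep 1 per min, event streams as logged).

The planted, effect-size-scaled links are the behaviors the pipeline is
meant to detect: lonelier participants spend *less* weekend-evening time
off campus (propensity 0.5 − 0.9·e·(latent − 0.5)), *less* weekday-evening
time at social-event houses, take *fewer* steps, shift *more* phone use
into the night, and sleep later. `effect_size = 0` severs every link, so
null cohorts provide the negative control for the whole pipeline. The
post-semester latent drifts by N(0, 0.09) plus an activity-linked
decrease, which makes unchanged loneliness the dominant change category
with small DL/IL minorities, as expected over a single semester. GPS noise is
10 m SD, so ≥90% of night samples fall within 100 m of home; per-stream
whole-day dropout is a generator option (default 5% in the analysis
scripts) used to exercise the missing-data policy.

What the generator does *not* emulate: platform differences between
phones, battery- or nonwear-induced gaps with structure (dropout is
uniform by day), GPS multipath or indoor drift, MAC randomization, and
any semester-time trend other than the latent drift. Passing tests
therefore demonstrate that the pipeline recovers planted effects of the
stated size under clean missingness — not that equally sized effects are
recoverable from field data.

# Problem sizes used in the shipped analyses and tests

The full design — 160 participants, 16 weeks, 45 segments, 200 stability
subsamples — is the configured default, but the shipped analysis scripts
and the acceptance checks run desk-scale versions chosen so the whole
chain reruns in minutes on one CPU: the analysis scripts use 32
participants over 6 weeks with semester-granularity segments; the
end-to-end recovery checks use cohorts of 30 over 4 weeks, night/evening
epochs crossed with all-days/weekends at semester granularity, 12
stability subsamples, and 3 effect plus 2 null seeds; combinatorial and
oracle checks run on purpose-built small inputs. These sizes are stated
here once and fixed; the planted effect size (1.0), the acceptance
margins and the statistical thresholds they are checked against are never
adjusted to the realized draws.

# Known limitations

* Place detection quality depends on DBSCAN's eps (30 m) and min_samples
  (5 at the 10-min cadence ≈ an hour of dwell); both are config keys
  because no canonical values exist for campus-scale GPS traces.
* The movement-regularity score is a normalized Lomb–Scargle power and is
  comparable between traces of similar length only.
* Stability selection among strongly collinear variants of the same
  behavior (e.g. minutes vs percent off campus) splits votes across the
  variants; interpretation should group features by family, as the
  rule-mining stage does implicitly through discretization.
* The ensemble's leave-one-out evaluation at small n has high variance;
  metrics from single seeds should not be over-read.
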