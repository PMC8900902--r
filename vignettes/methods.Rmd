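---
title: "Methods: sensor-triggered EMA compliance and detection validity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-triggered EMA compliance and detection validity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emawear)
```

## Overview

`emawear` analyses in-home family deployments in which a wrist-worn
sensor detects eating-related hand-to-mouth (H-t-M) gestures, a study
phone delivers two kinds of ecological momentary assessments (hourly
time-triggered questionnaires and eating event–triggered confirmation
questionnaires), and proximity beacons indicate presence at home. The
pipeline has five stages — detection, EMA protocol, participation
inference, compliance metrics, and detection validity — and is driven by
a synthetic deployment generator with known ground truth. This vignette
records the model behind each stage, the conventions and tunable
parameters, and the choices made where the design was genuinely open.

## Eating-event detection

The detection rule is: at least `min_gestures` (default 2) H-t-M
gestures within a 1-minute time frame form a detected eating event.
"Within a 1-minute time frame" is implemented as *single-linkage
chaining*: two gestures belong to the same cluster iff they are
connected by a chain of gestures with consecutive gaps of at most
`window_seconds` (default 60 s). The alternative reading — a fixed
calendar-minute bin — would split an eating bout that straddles a minute
boundary into undetectable fragments, which is clearly not what a
deployed on-line detector does. Because the deployed system's exact
windowing is not knowable from the outside, the window is a parameter,
and the package's tests verify the chaining semantics against a
brute-force transitive-closure oracle rather than against any specific
deployment.

Event start and end are the first and last gesture timestamps of the
cluster, at whole-second resolution. Events are therefore closed
intervals `[start_ts, end_ts]`; sensor minutes are half-open
`[m, m + 60 s)`. An event is kept only if beacon data are available for
at least one minute overlapping it; absent minute records count as
beacon-unavailable, so missing coverage is conservative (events are
dropped, never invented).

The raw inertial classifier that produces gesture timestamps is outside
the package's scope: detection operates on timestamps, and classifier
error is represented generatively (see the noise-burst mechanism below).

## EMA protocol conventions

* **Hour marks.** A time-triggered prompt fires at every clock-hour mark
  `t` with `window_start <= t <= window_end` (both ends inclusive,
  configurable via `inclusive_end`). A stated waking window of
  06:30–23:00 then yields prompts 07:00 through 23:00 — seventeen per
  day — which matches how such windows are described in practice; a
  window without any hour mark simply yields no prompts.
* **Event prompts** are sent `event_prompt_delay_seconds` (default 60 s,
  "shortly after") after a detected event ends and are suppressed if
  that moment falls outside the participant's window.
* **Delivery.** The scheduler sends regardless of network state; a
  prompt is received with probability `1 - prompt_delivery_failure_prob`
  and `received_ts = sent_ts` (latency is not modelled). Prompts sent
  but not received are removed from every downstream analysis.
* **Answered** means `answer_state` is `partial` or `complete`: a
  participant who opened the questionnaire and answered at least one
  item counted as compliant. For *validity* the stricter rule applies:
  an event prompt is usable iff its first question ("Were you eating or
  drinking just now?") was answered; otherwise the detection is
  *unverified* and excluded.
* The defer/"more time" pathway affects only answer-state bookkeeping;
  deferred content is identical to immediate content, so it is not
  modelled separately.
* Simultaneous pending prompts (an hourly prompt arriving while an event
  prompt is open) are treated as independent prompts.

The full item catalogue — affect battery for time-triggered prompts; the
eating-confirmation branch with eating type, social context,
started/kept-eating batteries, hunger and satiety sliders (0–100),
mindful-eating items, and affect for the "yes" branch; activity plus
affect for the "no" branch — ships as a versioned JSON resource
(`ema_items()`), and `validate_flow()` checks branch reachability and
response ranges against it.

## The participation algorithm

Hourly prompts reach the phone (which stays at home) whether or not the
participant is home, so raw received counts would understate compliance
badly. Participation is inferred from the data:

1. **EMA anchors.** If a participant answered a prompt at time `t`, they
   are participating on `[t − 15 min, t + 15 min)`. The anchor `t` is
   the prompt's `received_ts`: the package does not model a separate
   answer timestamp, and an interaction places the participant at the
   phone in that window regardless. The radius is configurable.
2. **Sensor minutes.** Outside anchor windows, a minute counts iff the
   accelerometer is available *and* indicates movement *and* beacon data
   are available. The movement threshold itself is upstream: `movement`
   arrives as a flag, generatively set by the simulator.
3. **Union.** Contiguous participating minutes merge into intervals and
   the union of both interval sets is the valid participation time.
   Because it is a union, the stated precedence of EMA anchors over
   sensor silence is automatic.

All intervals are half-open and normalized (sorted, disjoint, touching
intervals merged); a prompt is retained iff `received_ts` lies inside an
interval of its owner, so a prompt exactly at an interval's end bound is
excluded — one uniform convention instead of per-case boundary rules.
Anchor intervals are *not* clipped to the personalized window (a
participant answering just past their nominal window is still
participating); clipping is left to the caller if wanted. A built-in
self-consistency property follows: every answered prompt sits inside its
own anchor interval, so the algorithm can never discard an answered
prompt.

## Compliance metrics and models

Compliance for participant *i* is (EMAs answered)/(EMAs received at
home), computed per prompt type, and pooled at the overall, family, and
individual level with mean/SD/range dispersion across units; units with
zero retained prompts are flagged and excluded from dispersion.

The logistic models regress the 0/1 answered outcome on age, afternoon,
evening (reference morning: midnight–11:59:59; afternoon:
noon–16:59:59; evening: 17:00:00–23:59:59), weekend (Saturday/Sunday),
deployment day (1 + whole days since the family's start), female,
mother, father, and *others answered* — whether any other member of the
same family answered a retained prompt received within ±15 minutes of
the focal prompt. The pooled model additionally carries an
event-triggered prompt-type indicator. Choices worth recording:

* Observations are treated as **independent** plain-logistic rows, not
  as a mixed model with family or person random effects. That matches
  the conventional analysis this package implements and keeps the
  simulate-and-refit loop exact; it is also a documented limitation
  (standard errors ignore within-person clustering).
* The **social window** is evaluated on `received_ts` (sent, received,
  and answered times coincide for received prompts under the delivery
  model, so the distinction is moot in simulation; the window timestamp
  is config-exposed).
* Family roles other than mother/father are merged with the child
  **reference** category; the models contrast mothers and fathers only.
* **Wald 95% CIs** on the log-odds scale, exponentiated — the
  conventional reporting for this analysis — rather than profile
  likelihood.
* Separation and non-convergence are reported (error or warning), never
  silently returned.

`reference_model_coefficients()` bundles published reference estimates
for the three models from an in-field family deployment. They serve as
generator inputs for parameter-recovery experiments
(`simulate_observations()` + `recover_odds_ratios()`): covariates are
drawn to mimic the deployment mix (18.6/30.5/51.0% morning/afternoon/
evening, 2/7 weekend, 14-day deployments, 57.5/31.8/10.7%
child/mother/father, child ages 11–18, parent ages around 44). The
others-answered prevalence is not derivable from published margins and
is set to 0.5: top-of-hour prompts reach all family members
simultaneously, so co-answering within ±15 minutes is common. The
pooled reference set carries an unpublished prompt-type coefficient,
set to 0.

## Detection validity

A confirmed "yes" is a true positive, a "no" a false positive (with the
reported activity captured), an unanswered first question leaves the
detection unverified. Precision is TP/(TP + FP) **over verified
detections only** — unverified detections appear in neither numerator
nor denominator. Per-person proportions of correct detections use the
same ratio per participant; participants who received fewer than 3 event
prompts are excluded from group comparisons. Subgroup differences use
Mann-Whitney U (gender), Kruskal-Wallis (role), and Spearman rank
correlation (age, height), with midranks and the usual
normal/chi-square approximations under ties.

One numerical note: with 302 confirmed and 93 refuted detections out of
395 verified, the defining ratio gives 302/395 = 0.7646. A
reported-rounded figure of 0.77 circulates for this quantity; it is
inconsistent with those counts (it would require 304/395), so the
package returns the ratio its definition produces, 0.7646, and the test
suite pins exactly that. True negatives and false negatives are
unobservable under an event-triggered confirmation design, so accuracy,
recall, and F1 are deliberately absent.

## The synthetic deployment generator

Defaults describe the study conditions the package targets: 20 families
for 14 consecutive days, each family with one or two parents (85%
two-parent) and 1–4 participating children aged 11–18 (15/75/5/5%),
personalized windows starting 06:00–09:00 and ending 21:00–24:00 on
whole minutes.

* **Eating bouts** arrive as a homogeneous Poisson process (default 1
  bout/person-day at home) within the window, with uniform 2–20 min
  durations and within-bout gesture gaps uniform on 2–20 s — so every
  simulated bout satisfies the detection rule by construction. Bouts
  keep >60 s separation so detection maps bouts to events bijectively
  in the noise-free case. No distributional claim is intended: eating
  microstructure is not published, so all rates are configuration.
* **Noise gestures** (phone use, grooming) are isolated single gestures
  (>60 s from any other gesture, default 0.3/h). **Noise bursts**
  (default 0.15/person-day) are clusters of 2–4 non-eating gestures
  that survive detection — the generator's stand-in for classifier
  false positives, without which simulated precision would be
  identically the true-event confirmation rate.
* **Sensor minutes** are i.i.d. Bernoulli per minute (defaults:
  accelerometer availability 0.75, movement given availability 0.6,
  beacon 0.85); minutes overlapping a bout are fully sensed with
  probability 1 (eating at home while wearing the watch). Availability
  gaps are the model of watch-off and out-of-home time; there is no
  explicit location trace, since out-of-home data are discarded anyway.
* **Delivery failure** defaults to 0.1 (sent-but-not-received counts
  are not published; ~10% is a realistic in-home Wi-Fi loss rate).
  Confirmation behaviour defaults to 0.95 yes given a true bout and
  0.05 yes given a false detection (small self-report error).
* **Responses** are drawn prompt-by-prompt in timestamp order from the
  configured logistic model, so the others-answered covariate is
  evaluated causally against already-simulated answers.

What the generator does **not** emulate: circadian structure in eating
times (bouts are uniform within the window), serially correlated
non-response (fatigue enters only through the deployment-day
coefficient), device-specific failure bursts (delivery failures are
i.i.d.), and room-level beacon signal structure. Passing tests therefore
demonstrate that the pipeline's algebra and estimators are correct under
a faithful but simplified generative model — not that any particular
field deployment met its assumptions.

## Numerical choices and problem sizes

* Timestamps are naive local time stored as POSIXct in UTC (the study
  setting is single-timezone; no DST arithmetic is wanted), at
  whole-second resolution; sensor data are minute-grained.
* Interval normalization merges touching intervals, so "disjoint and
  non-adjacent" is an invariant of every interval set the package emits.
* Determinism: every generator accepts a seed; `simulate_deployment()`
  seeds once and runs sub-generators unseeded in a fixed order, so a
  configuration reproduces byte-identical outputs.
* Degenerate inputs: zero denominators raise errors (rates) or flags
  (per-unit dispersion, undersized test groups); unparseable rows and
  invariant violations are reported with row numbers at I/O boundaries.
* Test and experiment sizes were chosen as the smallest that make the
  statistical checks sharp: oracle-equivalence tests use hundreds of
  random gestures/minutes per replicate; Monte-Carlo probability
  recoveries use 100 replicates and 3-standard-error bands;
  odds-ratio recovery uses 20 replicates of 50,000 observations, which
  puts the Monte-Carlo standard error of each recovered OR near 0.01 —
  an order of magnitude below the rounding of the published values.
* Pipeline demonstrations use 2–4 families over 3–7 days; all metrics
  are invariant to scale except for the width of their sampling error.

## Known limitations

* Plain logistic regression ignores family/person clustering; recovered
  standard errors are correct only under the generator's independence.
* The participation algorithm can only be validated against its own
  definition (and the generator's ground truth); no external
  home-presence truth exists.
* Precision depends on the confirmation self-reports; social
  desirability in refusing to confirm eating would bias it and is not
  modelled.
* The gesture classifier is abstracted to timestamps plus a synthetic
  false-positive mechanism; conclusions about raw-signal performance
  are out of scope.
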