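# emawear

Compliance and detection-validity analysis for in-home family studies
that pair a wrist-worn eating-gesture sensor with ecological momentary
assessment (EMA).

## The problem

Field studies of family eating dynamics deploy, for about two weeks per
family, a smartwatch that detects eating-related hand-to-mouth (H-t-M)
gestures, a locked-down study phone that delivers mobile questionnaires,
and Bluetooth proximity beacons that indicate presence at home. Two EMA
protocols run side by side: *time-triggered* questionnaires every hour at
the top of the hour inside each participant's personalized waking window,
and *eating event–triggered* questionnaires sent shortly after the watch
detects a candidate eating event, asking "Were you eating or drinking
just now?". The self-reports are the only available ground truth for the
detector, and the phones receive hourly prompts whether or not the
participant is actually at home — so before any rate can be computed, the
analysis has to work out *when each participant was at home and
participating*.

`emawear` implements that analysis pipeline end to end, driven by a
synthetic deployment generator with known ground truth, so every stage is
testable without access to raw field data:

1. **Detection** — a cluster of ≥ 2 H-t-M gestures within a 1-minute time
   frame (single-linkage chaining of gaps ≤ 60 s) becomes a detected
   eating event; events without a beacon-covered minute are discarded.
2. **EMA engine** — hourly scheduling inside personal windows,
   event-triggered prompts, delivery failure, and answer-state
   bookkeeping (sent → received → answered, with partial answers).
3. **Participation algorithm** — a participant is *participating* for
   the 30-minute interval `[t − 15 min, t + 15 min)` around every
   answered prompt; outside those windows, for each minute in which the
   accelerometer is available *and* indicates movement *and* beacon data
   are available. Contiguous minutes merge, the union of both interval
   sets is the valid participation time, and only prompts received inside
   it are analysed.
4. **Compliance** — for participant *i*,

   `compliance_i = (EMAs answered by i) / (EMAs received at home by i)`

   computed overall and per prompt type, at the pooled, family, and
   individual level, plus logistic models of the answered/not-answered
   outcome on time of day, weekend, deployment day, age, gender, family
   role, and the social covariate *others answered* (another family
   member answered a prompt received within ±15 minutes).
5. **Validity** — detections confirmed "yes" are true positives, "no"
   false positives; `precision = TP / (TP + FP)` over verified
   detections, per-person proportions of correct detections (participants
   with < 3 event prompts excluded), and nonparametric subgroup tests
   (Mann-Whitney U, Kruskal-Wallis, Spearman). Negatives are unobservable
   by design, so no recall or F1 is ever reported.

## Worked example

```r
library(emawear)

cfg <- deployment_config(n_families = 4, deployment_days = 7, random_seed = 11)
res <- run_pipeline(cfg)
writeLines(pipeline_report(res)[1:8])
```

```
== deployment ==
participants 16, gestures 7758, true bouts 121, detected at-home events 139
prompts sent 1826, received 1646, retained after participation 1539 (93.50% of received)

== compliance ==
all / overall: 1471/1539 = 95.58%
all / family: 1471/1539 = 95.58% (unit mean 95.6%, SD 0.7%, range 94.6-96.2%)
all / individual: 1471/1539 = 95.58% (unit mean 95.6%, SD 2.1%, range 92.5-99.0%)
```

Of 1826 prompts the scheduler sent, 1646 reached a phone (10% simulated
delivery failure) and 1539 were received inside a valid participation
interval; 95.58% of those were answered. The validity block of the same
report reads:

```
event prompts 118: TP 94, FP 16, unverified 8; precision 0.8545
per-person correct proportion (n=14 included): mean 0.869, SD 0.142, range 0.625-1.000
```

118 detections triggered a retained confirmation prompt; 110 had their
first question answered (8 unverified), of which 94 confirmed eating, so
precision is 94/110 = 0.8545.

Published reference coefficient sets for the three compliance models are
bundled, and simulation-based parameter recovery is one call:

```r
rec <- recover_odds_ratios(reference_model_coefficients("time_triggered"),
                           n = 50000, seeds = 1:20)
mean(rec$odds_ratio[rec$term == "others_answered"])
#> [1] 2.083532
```

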