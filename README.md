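# antivea

Schedules, simulation, and scoring for the **ANTI-Vea** task — the
Attentional Networks Test for Interactions and Vigilance (executive and
arousal components). The task interleaves three trial types in every block:
flanker trials with tone (alerting) and spatial-cue (orienting)
manipulations, rare displaced-target trials probing *executive vigilance*
(signal detection: hits and false alarms), and countdown trials probing
*arousal vigilance* (reaction speed: mean/SD RT and lapses). One standard
session — six blocks of 48/16/16 trials, each in a fixed 4100 ms envelope,
32 min 48 s in total — yields 18 core indexes.

The package is for researchers who analyze (or plan studies around)
ANTI-Vea-style data and want the whole task-to-index chain testable
offline:

- **`build_session()`** — deterministic, seeded trial schedules for the
  full task and its sub-task versions (single/dual-task SART and PVT
  variants, thought probes, distractor slots), enforcing the exact
  per-block composition (48 ANTI = 2 tone x 3 cue x 2 congruency x 4, 16
  EV, 16 AV) and probe-spacing rules.
- **`simulate_cohort()`** — raw trial records from a generative model whose
  parameters *are* the scored quantities: additive RT effects on a shifted
  lognormal, block-linear hit/false-alarm probabilities, block-linear
  normal countdown RTs with a slow-tail lapse mixture.
- **`score_dataset()`** — the standard preprocessing (practice removal,
  incomplete-block / minimization / >25%-error exclusions, 200-1500 ms RT
  filter) and all core indexes plus signal-detection extensions
  (log-linear-corrected d' and criterion).
- **`split_half()`** — stratified split-half reliability with the
  Spearman-Brown correction, r_SB = 2r / (1 + r).
- **`cohort_preset("inlab_reference")`** — cohort parameters calibrated by
  `calibrate_preset()` so that the *expected scored indexes* equal the
  published normative means (e.g. base RT = overall RT − alerting/2 −
  congruency/2 = 587.5 ms; block-1 hit probability = hits − 2.5 x hits
  slope = 77.965%).

Everything is tidyverse-shaped: functions take and return tibbles, results
support `tidy()`, `glance()`, and `autoplot()`.

## The indexes in brief

For flanker (ANTI) trials, with correct responses inside 200–1500 ms:
overall RT/errors; alerting = no-tone − tone (no-cue trials); orienting =
invalid − valid; congruency = incongruent − congruent. For executive
vigilance: hits% on displaced-target trials, false alarms% on the
*fa-difficult* flanker subset (target jitter > 2 px from an adjacent
flanker), and their per-block OLS slopes; d' = z(H) − z(FA) and
c = −(z(H) + z(FA))/2 after the (x + 0.5)/(n + 1) correction. For arousal
vigilance: mean RT, SD RT, lapses% (RT > 600 ms or no response), and their
slopes.

## Worked example

```r
library(antivea)

cfg   <- task_config(participant_code = "1234")   # standard 6-block session
sched <- build_session(cfg, seed = 11)
nrow(sched)                      # 480
schedule_duration(sched) / 60000 # 32.8 minutes

sim    <- simulate_cohort(cohort_preset("inlab_reference"), cfg,
                          n = 25, seed = 11)
scores <- score_dataset(sim$trials)
scores
#> ANTI-Vea scoring report
#>   sessions: 25 in, 25 scored, 0 excluded
#>   core indexes, M (SD) over scored sessions:
#>     overall_rt_ms                652.98 (99.67)
#>     overall_errors_pct             5.92 (3.72)
#>     alerting_rt_ms                43.35 (33.68)
#>     ...
#>     hits_pct                      79.38 (16.05)
#>     hits_slope_pct_per_block      -1.22 (3.57)
#>     av_mean_rt_ms                489.09 (11.86)
#>     lapses_pct                    11.12 (2.83)
#>     ...
```

The cohort means sit near the in-lab normative values the preset was
calibrated to (overall RT 629 ms, hits 73.24%, AV mean RT 491 ms, lapses
11.35%) up to sampling noise at n = 25. Reliability reproduces the
characteristic pattern that difference scores are far less reliable than
overall scores:

```r
split_half(scores$trials,
           indexes = c("overall_rt_ms", "alerting_rt_ms", "hits_pct"))
#>   index          scheme   n_participants n_splits r_half  r_sb
#> 1 overall_rt_ms  odd_even             25        1  0.990 0.995
#> 2 alerting_rt_ms odd_even             25        1  0.231 0.375
#> 3 hits_pct       odd_even             25        1  0.915 0.956
```

A thin command line sits over the same functions
(`inst/cli/antivea.R`): `build-schedule`, `simulate`, `score`,
`reliability`, and `demo`, with Table-style setting keys (`pc`, `B`, `no`,
`dif`, `st`, `probes`, ...) as flags or a YAML/JSON config file.

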