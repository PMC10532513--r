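---
title: "Models and methods behind antivea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind antivea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antivea)
```

## What the package models

The ANTI-Vea task measures the three attentional networks (phasic
alerting, orienting, executive control) and two dissociable vigilance
components in a single session. Each experimental block mixes, in random
order, 48 flanker (ANTI) trials carrying a 2 (warning tone) x 3 (visual
cue: valid, invalid, none) x 2 (flanker congruency) factorial, 16
executive-vigilance (EV) trials in which the central arrow is vertically
displaced and must be detected with the spacebar, and 16 arousal-vigilance
(AV) trials in which a millisecond countdown must be stopped as fast as
possible. Every timed trial occupies a fixed 4100 ms envelope, so the
standard six-block session lasts exactly 480 x 4.1 s = 32 min 48 s.

`antivea` implements the full chain — schedule, raw data, indexes,
reliability — so that the scoring pipeline can be verified against data
with *known* generative parameters. The design principle throughout is
that every generative parameter is, by construction, the population
counterpart of a scored index.

## Schedules

`build_session()` is a pure function of a configuration and a seed. Within
each block the ANTI factorial is covered exactly four times (once per
target location x direction), EV trials are 8 upward and 8 downward
displacements with the 12 factorial cells covered once plus 4 cells chosen
by a seeded rotation (16 trials cannot cover 12 cells evenly), and AV
trials carry a not-applicable sentinel on the manipulation fields. The
single per-session random stream is consumed in a fixed order (cell
choices, then position shuffles, then jitters, then probe placement),
which is what makes identical (config, seed) pairs byte-identical.

Choices the task description leaves open, fixed here as documented
constants:

- **Jitter law.** Each of the five arrows receives an independent uniform
  integer vertical jitter in [-noise, +noise] px. This is the simplest law
  consistent with an ordinal 1-6 "noise" setting, and it makes the
  fa-difficult fraction exactly enumerable.
- **fa-difficult fraction.** A flanker trial enters the false-alarm
  denominator when the target's jitter differs by more than 2 px from at
  least one adjacent flanker. The two comparisons share the target's
  jitter, so they are not independent: enumerating the (flanker, target,
  flanker) triple at noise = 2 gives
  $1 - \mathbb{E}_x[P(|x - j| \le 2)^2] = 1 - 75/125 = 0.4$ exactly
  (`fa_difficult_fraction()`), and the Monte-Carlo fraction in built
  schedules converges there. Treating the two sides as independent would
  instead give $1 - (19/25)^2 \approx 0.4224$; that shortcut is wrong, and
  the tests pin the enumerated value.
- **Difficulty map.** The ordinal difficulty 1 (hardest) .. 5 (easiest)
  maps to displacement magnitudes 6, 8, 10, 12, 14 px
  (`difficulty_displacement_px()`). Any monotone map is admissible; this
  one is a documented constant, not an empirical claim.
- **Thought probes** are inserted with at least five task trials between
  consecutive probes (sorted-offset sampling keeps the gap constraint for
  every seed) and are self-paced: they do not advance the 4100 ms grid,
  so the stated session durations hold for the probe-free standard format.
- **Practice** (four blocks) is structural only: quarter-size composition
  (12/4/4), flagged `practice`, excluded from the timed duration. Feedback
  logic is out of scope.
- **SART-only versions.** Both reduced SART versions present the go and
  no-go stimulus stream (48 ANTI + 16 EV per block); the *Go* version
  expects spacebar on displaced targets only, the *NoGo* version expects a
  keypress on every non-displaced trial and withholding on displaced ones.

## The generative model

Per participant (`participant_params()`):

| Parameter | Units | In-lab preset | Meaning |
|---|---|---|---|
| `rt_base_ms` | ms | 587.5 | mean correct RT, tone + no-cue + congruent cell |
| `alerting_ms` | ms | 40 | no-tone minus tone cost |
| `orienting_ms` | ms | 40 | invalid minus valid cost (±half around no-cue) |
| `congruency_ms` | ms | 43 | incongruent minus congruent cost |
| `rt_sigma_ms` | ms | 120 | within-person trial SD (free dial) |
| `err_base`, `err_*_delta` | prob | solved | error rate and condition deltas |
| `anticipation_rate` | prob | 0.02 | RTs replaced by uniform 80-199 ms |
| `ev_hit_p1`, `ev_hit_slope` | prob, /block | solved | block-linear hit path |
| `fa_p1`, `fa_slope` | prob, /block | solved | block-linear FA path (fa-difficult trials only) |
| `av_mu1_ms`, `av_mu_slope_ms` | ms | 481, 4 | block-linear countdown RT mean |
| `av_sigma1_ms`, `av_sigma_slope_ms` | ms | 80, 4 | block-linear countdown RT SD |
| `av_lapse_mix` | prob | 0 | slow uniform 600-1000 ms tail weight |

Flanker RTs follow a 200 ms **shifted lognormal** with the additive cell
mean and SD `rt_sigma_ms`. No trial-level distribution is prescribed by
the task itself; the lognormal gives realistic right skew while the
mean/SD parameterization keeps every calibration identity exact (an
ex-Gaussian would serve equally; only the mean structure matters for the
indexes). The orienting effect is split ±half across invalid/valid so the
no-cue cell sits at the midpoint — this is what makes the orienting index
equal its generative parameter and lets orienting cancel out of overall
RT. Anticipations (uniform 80-199 ms) are removed by the RT filter, so
they add realism without moving RT indexes. False alarms arise only on
fa-difficult trials, where the jitter makes a displacement plausible; easy
trials have FA probability 0. EV hit RTs are the flanker draw + 50 ms (an
extension index only). AV RTs are block-linear normal mixed with a slow
uniform 600-1000 ms tail; draws reaching the 1000 ms countdown limit
become omissions, so responded AV RTs always lie in (0, 1000].

The within-person noise `rt_sigma_ms = 120` ms is a free dial: published
tables report only between-person SDs, and no index mean identifies it.
Its value (and hence every simulated split-half coefficient) is
non-normative; only the *ordering* of reliabilities is a model prediction.

## Calibration: making expected scores equal the targets

`calibrate_preset()` maps a normative index table
(`reference_index_targets()`, in-lab and online columns) to cohort
parameters such that the **expected scored indexes equal the targets**:

- closed-form identities where the scoring is linear:
  `rt_base = overall_rt − alerting/2 − congruency/2` (tone and congruency
  each hit half the trials; orienting cancels across cue thirds),
  `p1 = index − 2.5 × slope` for the block-linear paths (blocks 1..6
  average at 3.5);
- the lapse identity
  `lapses = (1 − mix) · mean_b P(N(μ_b, σ_b) > 600) + mix`, solved for
  `mix` and clamped at 0 with a message when the normal drift already
  exceeds the target (it does, marginally, at both reference presets:
  11.38% vs the 11.35% in-lab target);
- **truncation inversion**: participants are drawn from truncated normals
  over each field's legal range, and truncation shifts means (e.g. a
  naive ev_hit_p1 mean of 0.78 with SD 0.173 truncated to [0, 1] would
  lose ~3.4 points of hits). For every bounded field the underlying normal
  mean is solved numerically so the *truncated* population mean equals the
  identified value;
- **clipping-aware path solving**: block probabilities are
  `clip01(p1 + slope · (b − 1))`; near the ceiling this attenuates
  positive slope draws across the cohort (and symmetrically at the
  floor), which would bias the scored hits slope by roughly −0.5 %/block
  under the naive identity. The (p1, slope) pairs for hits and false
  alarms are therefore solved jointly against the population expectation
  of the clipped path (midpoint-quantile quadrature, deterministic);
- **error-mass accounting**: a spacebar false alarm is an incorrect
  response on a flanker trial, so the direction-error parameters only
  need to produce the remainder of the target error rate after the FA
  contribution (fa-difficult fraction x FA rate), with `err_base` solved
  against the cohort expectation of the per-cell clipped error
  probability.

Between-person SDs come from the normative SD columns for fields whose
scored index is a linear readout (RT effects, error indexes, EV paths).
The AV fields are left homogeneous (SD 0) in the shipped presets: under
the Gaussian AV law the lapse probability is convex in μ and σ, so
normative between-person dispersion (62/39 ms) would raise the cohort
lapse expectation from ~11.4% to ~16-18% by Jensen's inequality,
contradicting the published lapse mean that the calibration contract must
reproduce. This is a recognized limitation of the Gaussian family — in
real data, person-level skew ties RT variability and lapses together —
and it means the presets do not model between-person AV differences.

## Scoring rules

Practice rows are dropped; sessions are excluded for incomplete blocks
(always), minimization (under `screen_policy = "full_only"`), and flanker
error rates above 25% (under `validity_policy = "valid_only"`), each with
a named reason. RT indexes use correct flanker responses within
200-1500 ms; error indexes use all flanker trials; the FA denominator
keeps every fa-difficult trial regardless of RT validity (a debatable
platform detail, fixed here and documented). Alerting is computed on
no-cue trials only; orienting and congruency on all flanker trials.
Slopes are unweighted per-block OLS on block numbers 1..B, missing when
fewer than two block values exist. AV mean/SD use responded trials only,
while lapses count both slow (> 600 ms) and omitted trials — an
unresponded trial has no RT but is still a lapse. Signal detection uses
the log-linear (x + 0.5)/(n + 1) correction so d' and c stay finite at 0%
and 100%. Zero fa-difficult trials yield missing FA indexes with a
warning, never a division by zero.

## Reliability

`split_half()` partitions trials within participant, stratified by kind,
block, the flanker factorial cell, and the fa-difficult flag, so both
halves support every index; halves are scored by the same scorer and
correlated across participants, then corrected with the Spearman-Brown
prophecy formula (the emitted `r_half`/`r_sb` pair always satisfies the
identity exactly). The default odd-even scheme is deterministic; a seeded
random-splits mode averages over partitions and reports the spread. The
model predicts — and the tests assert — only the qualitative pattern seen
in published data: overall scores highly reliable, difference scores
(alerting, orienting, congruency) much less so, because subtracting two
noisy condition means removes most stable between-person variance while
keeping the trial noise. Exact coefficients depend on the non-normative
within-person noise dial and on real-data variance components the
normative tables do not publish, so no numeric reproduction is claimed.

## Numerical choices

Truncated-normal moments and quantiles are computed in whichever tail
keeps precision (the naive `pnorm(b) − pnorm(a)` underflows once bounds
sit ~9 SDs out, which silently corrupted an early version of the
calibration). The quadrature for the clipped-path solver uses 161
midpoint quantiles per margin; the error-rate solver uses a fixed-seed
Monte-Carlo expectation (40,000 draws) inside a monotone root-finder, so
calibration is deterministic. Probability paths are clipped per block;
AV RT draws are floored at 1 ms. Degenerate inputs (empty tables, missing
kinds, single-block sessions) yield missing indexes or named errors, not
crashes.

## What the simulator does and does not emulate

It emulates: the trial mixture and factorial balance, additive RT
effects, block-linear vigilance decrement in hits/FA and block-linear
drift in AV mean/SD/lapses, anticipations, omissions, countdown
expiry, and population heterogeneity for the attentional and EV fields.
It does **not** emulate: learning or fatigue beyond linear block trends,
sequential effects (post-error slowing, congruency sequence), RT
autocorrelation, distractor responses (distractor slots are scheduled
only), genuine mind-wandering dynamics (probe ratings are uniform
placeholders), device latency, or correlations between parameters across
people (fields are drawn independently). Passing parameter-recovery tests
therefore shows that the *scoring pipeline* is faithful to its
definitions — not that real data obey this generative family.

## Problem sizes

The shipped checks use sizes chosen to make sampling error small relative
to the tolerances while staying quick to run: the recovery check
simulates 200 participants (2-standard-error bands on all seven headline
indexes), the reliability ordering uses 60, the fa-difficult convergence
uses 100,000 trials against the enumerated 0.4, and unit tests use 1-2
block cohorts of ~8 participants.
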