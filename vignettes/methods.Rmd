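---
title: "Screen-time metrics, symptom aggregation, and the specification curve: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screen-time metrics, symptom aggregation, and the specification curve: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and design choices behind
`screensca`. The package implements the analysis pipeline of a smartphone
digital-phenotyping study in serious mental illness: objective screen-time
metrics derived from passive screen on/off logs are related to repeated
self-reported symptoms and smartphone-administered cognition scores, at the
cohort level (pooled regression, specification curve) and at the individual
level (idiographic regressions).

## From raw events to screen metrics

The atomic input is a stream of `"Screen On"` / `"Screen Off"` events per
participant. `sessionize()` pairs each On with the next Off to form a usage
**session**; raw **screen time** for a day is the sum of session durations
in seconds. Two further metrics follow: **session time**, the day's screen
time divided by its number of sessions (the mean session duration), and the
**number of checks**, sessions lasting strictly less than 15 seconds — the
conventional operationalisation of habitual checking behaviour. The number
of sessions itself is carried as a fourth metric.

Real event logs are imperfect, so the sessionizer has an explicit repair
policy rather than an implicit one:

* an On with no following Off before the next On (or before the stream
  ends) is dropped — a duration cannot be attributed without inventing it;
* an Off with no pending On is likewise dropped;
* records with unparseable timestamps or unknown states are rejected;
* all three counts are logged on the returned object so data-quality
  problems are visible, never silent.

Days are wall-clock calendar days in a single configurable study timezone
(default UTC). A session that crosses local midnight is split at the
boundary; each fragment is attributed to its own day and its check status
is re-evaluated from the fragment duration. This keeps the conservation
invariant exact — summed daily screen time equals summed session durations
— at the cost of occasionally reclassifying the tail of a long evening
session. Zero-duration sessions (On and Off at the same instant) are kept
and count as checks, since 0 < 15. Days with no usage produce no row:
absence of data is missingness, never a zero.

## Survey aggregation

Surveys arrive as total scores per instrument: mood (PHQ-9, 0–27), anxiety
(GAD-7, 0–21), sleep and sociability (no named instrument; the package
fixes a documented 0–10 scale, since only the range matters downstream),
and a smartphone cognition score (a Trails-B-style task summary combining
accuracy and error rate, treated as an opaque unbounded real). When more
than one response to the same instrument lands on one calendar day, the
day's value is the arithmetic mean — two PHQ-9 totals of 10 and 11 become
10.5. Scores outside an instrument's range are rejected and logged.
Response dates use the same study timezone as the screen metrics, so the
independent and dependent variables share one day grid and can be paired
"for a given day".

## Cohort inclusion

Two filters reproduce the study's inclusion logic: a participant must have
(a) at least one self-reported survey response — cognition tests are listed
separately from self-report and do not count — and (b) at least five
*consecutive* calendar days each with at least one session. The stricter
consecutive reading is adopted (and configurable) because five consecutive
days is the established minimum for inferring typical usage. The exclusion
report names every removed participant and the criterion(s) failed, and
together with the included roster partitions the roster exactly. The
analysis table joins daily metrics (the spine — only days with usage
appear), daily symptoms, and roster attributes; the age bracket splits
strictly at 30 years.

## Cognition analyses

**Baseline.** Per SZ participant, each screen metric is summarised as the
mean of its daily values over the participant's first 30 study days
(counted from their first recorded usage day; the summary statistic is the
mean and is configurable, since nothing pins it down further). Each of the
4 metrics is correlated with each of the 6 BACS subdomains by Spearman rank
correlation with average ranks for ties, giving 24 tests, adjusted jointly
by Benjamini–Hochberg (the canonical false-discovery-rate procedure;
per-metric adjustment is available as an option).

**Longitudinal.** Daily cognition scores are regressed by OLS on the four
daily screen metrics, pooling participant-days within a diagnostic group.
Degrees of freedom are therefore (4, n − 5) over pooled rows, the
convention that reproduces a denominator df of 144 from 149 complete rows.
Pooling ignores within-participant correlation by design — the reported F
and R² follow the pooled convention — and no clustering correction is
applied to the headline fit; users who want conservative inference should
treat these p values as optimistic.

## The specification-curve engine

A **specification** is one fully determined analytic choice: an independent
variable (one of the four screen metrics), a dependent variable (mood,
anxiety, sleep, social), a model family (linear, or generalized linear with
Gaussian family and identity link), a covariate set (none, or gender coded
male vs female), a diagnostic-group subset (SZ, HC, all) and an age-bracket
subset (under 30, 30+, all). The default menus yield the full Cartesian
product of 4 × 4 × 2 × 2 × 3 × 3 = 576 specifications in deterministic
lexicographic order. The menus are fully configurable; the source study
reports "over 600 combinations" without an enumerable menu, so the package
documents its default grid rather than pretending to recover that count.

Per specification, rows are restricted to the subsets and to days where
both variables are present; participants with gender recorded as "other"
are dropped only when gender is a covariate (the covariate contrasts male
vs female). Both variables are z-standardized *within the subset* before
fitting — estimates across specifications are then comparable on one axis,
which is what an ordered curve requires; a raw-scale option exists. The
reported estimate is the coefficient on the screen metric. Specifications
with fewer than `min_n = 10` observations are skipped (reported, not
dropped); a constant variable or a numerical failure is recorded as a
failed specification with its message, never as a spurious zero and never
as a crash. Because the generalized-linear family defaults to Gaussian with
identity link, the lm/glm pair differ only in fitting route; both are
retained because both families belong to the enumerated analytic space.
The curve summary reports the median estimate, the sign shares, the share
of p values below alpha, and the extreme specifications; the two-panel
plot shows estimates sorted ascending over an indicator matrix of choices.
No multiple-testing correction is applied across specifications — the
curve is a descriptive display of analytic flexibility, not a joint test.

## Individual-level regressions

Participants with at least one daily score in *every* one of the four
self-report categories enter the idiographic analysis. Per participant and
instrument, the raw daily symptom score is regressed on daily screen time
in hours (seconds / 3600, so slopes read as score points per hour). Raw
scales are used deliberately: individual effects are meant to be read in
instrument units, and their spread across people is the finding. Fits need
at least 3 paired days (slope plus intercept leave no residual df below
that); shorter pairs are omitted and logged. Estimates are sorted
descending within group, and group digests (mean, SD, min, max) are exact
arithmetic over the reported estimates.

## The synthetic-cohort generator

Every stage is testable without participant data because the generator
emulates all three inputs with known ground truth.

* **Roster** — `n_sz = 54` and `n_hc = 34` by default (the published cohort
  composition), uniform integer ages over a range straddling 30, gender
  dominated by male/female with a small "other" share, and six baseline
  BACS subdomain scores for SZ participants only.
* **Events** — per participant-day (outside whole-day dropout,
  `dropout_prob = 0.1`), a Poisson number of sessions around
  `sessions_per_day_mean = 40`; each session is a check with probability
  `check_fraction = 0.5` (uniform 1–14.5 s) or a long session (15 s plus a
  lognormal excess, `meanlog = 4`, `sdlog = 1`). Start times are uniform
  within waking hours (08:00–23:00) and redrawn on overlap; a final pass
  enforces strict non-overlap across midnight spills, so generated streams
  are always valid alternating logs. A shared lognormal **day-intensity
  factor** (`day_intensity_sd = 0.4`, mean 1) multiplies both the session
  rate and long-session durations: busy days have more sessions, more
  checks and more screen time at once, reproducing the strong positive
  cross-correlation of daily screen metrics seen in real usage logs.
  Defaults are conventional rather than calibrated — the source study
  reports no distributional facts about observed screen time.
* **Surveys** — each instrument is scheduled twice weekly (the
  ten-surveys-per-week protocol); a scheduled response materializes with
  probability 0.75. The day's score couples linearly to that day's
  standardized screen time through a per-participant slope
  `b_i = true_effect + N(0, effect_sd²)`, plus a per
  participant-instrument random intercept (`ranef_sd = 0.5`) and day
  noise, then is clipped to the instrument range.

`true_effect` is *defined* as the standardized slope of daily symptom on
standardized daily screen time. The generator enforces this with a
variance budget: residual day-level noise gets standard deviation
`noise_sd · sqrt(max(1 − b² − effect_sd² − ranef_sd², 0.01))`, so with
`noise_sd = 1` the latent score has unit variance and the pooled
z(score)-on-z(screen time) slope equals `true_effect` in expectation. Two
caveats are documented rather than hidden: range clipping attenuates the
realized slope of narrow-range instruments (sleep and social span only
±2.5 generator SDs, so their slopes shrink by several percent under
heavy-tailed screen time), and within-subset standardization in the SCA
can differ slightly from the pooled standardization used at generation.
For the idiographic analyses, `effect_scale = "per_hour"` instead couples
scores at `true_effect` raw points per hour of screen time — the same
scale `fit_individuals()` estimates on — which is the only scale on which
per-participant slope recovery is well-posed.

What the generator does *not* emulate: app-level content, notifications,
circadian within-day structure beyond the waking window, event-level
(rather than day-level) missingness, item-level PHQ-9/GAD-7 responses, and
any mechanism by which symptoms drive later usage (coupling is
contemporaneous and unidirectional). Passing recovery tests therefore show
that the pipeline estimates what the generative model encodes — not that
real screen-symptom effects exist or are identified.

## Numerical conventions and test scales

Checks use strict inequality (< 15 s). Ties in Spearman correlations use
average ranks. BH-adjusted p values are capped at 1. Standardization uses
the sample SD (n − 1). Specifications failing for constant inputs name the
offending column. All randomness flows through explicit integer seeds;
re-running any stage, or the whole pipeline, with the same configuration
is byte-identical.

The test suite exercises the pipeline at deliberately chosen scales: the
sessionization oracle on 1,000 random streams; the cohort filter against a
brute-force longest-run oracle on 500 random calendars; BH against its
closed-form oracle on 100 random p-vectors plus a 500-replicate null
calibration of the 24-test family; the specification curve on full
88-participant, 84-day cohorts both under the null (calibration of the
median and of the share of p < .05) and under a uniform standardized
effect of 0.3 (recovery); and the idiographic stage on 200 participants
with per-participant effects drawn from N(0.5, 0.2²) points per hour, with
day-level noise set so the mean-recovery check has adequate power. These
sizes are the package's own choices for a fast, reproducible suite.

## Known limitations

Pooled OLS p values ignore within-participant clustering (a
cluster-robust option is available for the cognition fit's predictors via
the returned `lm` object and standard sandwich tooling, but the headline
numbers follow the pooled convention). The specification curve is
descriptive; no permutation or bootstrap inference under the null is
performed. The "first month" summary statistic, the consecutive-day
reading of the usage cutoff, and the joint (rather than per-metric) FDR
adjustment are all documented conventions with configurable alternatives,
since the underlying choices are not fully determined by any published
description.
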