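# screensca

Smartphone screen-time metrics, daily symptom aggregation, and
specification-curve analysis for digital-phenotyping studies in serious
mental illness.

Passive-sensing apps record every `Screen On` / `Screen Off` transition on a
participant's phone. This package turns those logs, together with repeated
smartphone surveys (PHQ-9 mood, GAD-7 anxiety, sleep, sociability) and a
smartphone cognition task score, into the analyses a psychiatric
digital-phenotyping study runs: it is written for researchers who have
long-format event and survey streams and want a tested, reproducible path
from raw logs to effect estimates.

## What it computes

**Screen metrics.** Sessions are On→Off intervals; per participant-day the
pipeline derives raw screen time (s), number of sessions, session time
(screen time / sessions), and the number of *checks* — sessions under 15 s,
a proxy for habitual phone preoccupation. Sessions crossing midnight are
split at the day boundary; malformed event subsequences are dropped and
logged.

**Cohort rules.** Participants need ≥ 1 self-reported survey and ≥ 5
consecutive days of smartphone usage to enter the analyses.

**Cognition.** Spearman correlations (Benjamini–Hochberg FDR across all
4 × 6 = 24 tests) between first-month screen metrics and baseline BACS
subdomains; pooled OLS of daily cognition scores on the four metrics with
the overall *F*(4, n − 5), p, and adjusted R².

**Specification curve.** Every combination of independent variable (4
metrics), dependent variable (4 symptom instruments), model family (lm, or
Gaussian-identity glm), gender covariate (with/without), diagnostic-group
subset (SZ/HC/all) and age-bracket subset (<30 / ≥30 / all) — 576
specifications by default — each fitted on within-subset z-standardized
variables:

    z(y) = β · z(x) [+ γ · gender] + ε

and displayed as the ordered curve of β̂ with its variable-indicator panel.

**Individual-level effects.** Per participant × instrument, raw daily
symptom score on daily screen hours (OLS, ≥ 3 paired days), sorted within
diagnostic group — the idiographic heterogeneity that pooled fits hide.

**Synthetic cohort.** `synthetic_config()` / `simulate_study()` generate a
full study — roster, event stream, surveys — with known ground-truth
couplings (standardized slopes, or raw points-per-hour for the individual
analysis), so every stage is testable without participant data. See the
methods vignette (`vignettes/methods.Rmd`) for the generative model.

## Worked example

The one number everyone checks first — two same-day PHQ-9 totals of 10 and
11 average to 10.5:

```r
library(screensca)
r <- tibble::tibble(
  participant_id = "P001",
  timestamp = as.POSIXct("2023-01-02 09:00:00", tz = "UTC") + c(0, 7200),
  instrument = "mood", score = c(10, 11))
aggregate_daily(r)$mood
#> [1] 10.5
```

A full synthetic run, 54 SZ + 34 HC over 90 days (this is
`analysis/01_simulate.R` … `06_individual.R`; each script prints what it
found and writes its tables under `results/`):

```
$ Rscript analysis/01_simulate.R
roster: 88 participants (54 SZ, 34 HC)
events: 568242 screen on/off records

$ Rscript analysis/02_sessionize.R
284121 sessions over 7115 participant-days
mean daily screen time: 42.5 min; mean checks/day: 20.0; mean session time: 56 s

$ Rscript analysis/04_cognition.R
baseline screen: rho in [-0.20, 0.29]; 0 of 24 tests significant after FDR
Cognition ~ screen metrics (SZ): F(4,961) = 6.74, p = 2.37e-05, adj R^2 = 0.023, n = 966

$ Rscript analysis/05_sca.R
Specification curve: 576 specs (576 fit, 0 skipped, 0 failed)
  estimates -0.209 .. 0.214, median 0.041; 43.4% p < alpha
most negative: social ~ session_time (linear, none, SZ/over30), beta = -0.21
most positive: sleep ~ session_time (linear, gender, HC/under30), beta = 0.21
```

Reading this: the demo cohort was generated with heterogeneous true
couplings (e.g. positive mood–screen, negative social–screen in SZ), and
the curve shows exactly that spread — estimates of both signs whose
extremes sit in the subgroups that carry the generative effects, while the
baseline cognition screen is null, as generated. The equivalent single
call is `run_pipeline(list(synthetic = synthetic_config(...)), out_dir)`,
which also writes a run log and the resolved configuration and is
byte-identical across reruns with the same seed.

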