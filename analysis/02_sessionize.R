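#!/usr/bin/env Rscript
# Stage 2 — sessionization and daily screen metrics.
#
# Pairs screen on/off events into usage sessions and aggregates them to the
# participant-day grid: screen time, number of sessions, session time, and
# habitual checks (< 15 s).

suppressMessages(library(screensca))

events <- read_events("results/inputs/events.csv")
sessions <- sessionize(events)
dm <- daily_metrics(sessions)

readr::write_csv(dm, "results/daily_metrics.csv")

cat(sprintf("%d sessions over %d participant-days\n",
            nrow(sessions), nrow(dm)))
cat(sprintf("mean daily screen time: %.1f min; mean checks/day: %.1f; mean session time: %.0f s\n",
            mean(dm$screen_time_s) / 60, mean(dm$n_checks),
            mean(dm$session_time_s)))
cat(sprintf("%.1f%% of sessions are habitual checks\n",
            100 * mean(sessions$is_check)))
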