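#!/usr/bin/env Rscript
# Stage 3 — survey aggregation, inclusion filters, analysis table.
#
# Averages same-day survey scores per instrument, applies the two inclusion
# rules (at least one self-reported survey; at least 5 consecutive days of
# smartphone usage), and joins metrics, symptoms and roster attributes into
# the participant-day analysis table all models consume.

suppressMessages(library(screensca))

dm <- readr::read_csv("results/daily_metrics.csv", show_col_types = FALSE)
surveys <- read_surveys("results/inputs/surveys.csv")
roster <- read_roster("results/inputs/roster.csv")

ds <- aggregate_daily(surveys)
flt <- filter_cohort(roster, dm, ds)
tbl <- build_analysis_table(flt$included, dm, ds)

readr::write_csv(ds, "results/daily_symptoms.csv")
readr::write_csv(flt$exclusions, "results/exclusions.csv")
readr::write_csv(tbl, "results/analysis_table.csv")

cat(sprintf("included %d of %d participants; %d excluded\n",
            nrow(flt$included), nrow(roster), nrow(flt$exclusions)))
if (nrow(flt$exclusions) > 0) print(table(flt$exclusions$reason))
cat(sprintf("analysis table: %d participant-day rows\n", nrow(tbl)))
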