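#!/usr/bin/env Rscript
# Stage 6 — individual-level regressions.
#
# For every participant with responses in all four survey categories, fits
# daily symptom score on daily screen time (hours), exposing the
# between-person heterogeneity that the pooled models average away.

suppressMessages(library(screensca))

tbl <- readr::read_csv("results/analysis_table.csv", show_col_types = FALSE)

el <- eligible_participants(tbl)
ind <- fit_individuals(tbl, el)
isum <- summarize_individuals(ind)

readr::write_csv(ind, "results/individual_estimates.csv")
readr::write_csv(isum, "results/individual_summary.csv")

cat(sprintf("%d participants eligible (all four survey categories)\n",
            length(el)))
print(as.data.frame(isum))

p <- plot_individuals(ind)
ggplot2::ggsave("results/individual_effects.png", p, width = 9, height = 5,
                dpi = 150)
cat("figure written to results/individual_effects.png\n")
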