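#!/usr/bin/env Rscript
# Stage 5 — specification-curve analysis.
#
# Enumerates all 576 combinations of independent variable, dependent
# variable, model family, gender covariate, diagnostic-group subset and
# age-bracket subset; fits each on the analysis table; writes the ordered
# curve, its digest, and the two-panel figure.

suppressMessages(library(screensca))

tbl <- readr::read_csv("results/analysis_table.csv", show_col_types = FALSE)

grid <- build_grid()
sca <- run_sca(grid, tbl)
readr::write_csv(sca$results, "results/sca_results.csv")
readr::write_csv(sca$summary, "results/sca_summary.csv")

print(sca)
s <- sca$summary
worst <- sca$results[sca$results$spec_id == s$min_spec_id, ]
best <- sca$results[sca$results$spec_id == s$max_spec_id, ]
cat(sprintf("most negative: %s ~ %s (%s, %s, %s/%s), beta = %.2f\n",
            worst$y, worst$x, worst$model, worst$covariates,
            worst$subset_group, worst$subset_age, worst$estimate))
cat(sprintf("most positive: %s ~ %s (%s, %s, %s/%s), beta = %.2f\n",
            best$y, best$x, best$model, best$covariates,
            best$subset_group, best$subset_age, best$estimate))

p <- plot_curve(sca)
ggplot2::ggsave("results/sca_curve.png", p, width = 10, height = 7, dpi = 150)
cat("figure written to results/sca_curve.png\n")
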