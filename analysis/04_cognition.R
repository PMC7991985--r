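#!/usr/bin/env Rscript
# Stage 4 — cognition analyses.
#
# Baseline: Spearman correlations (BH-adjusted across all 24 tests) between
# first-month screen metrics and the six BACS subdomains in the SZ group.
# Longitudinal: pooled OLS of the daily smartphone cognition score on the
# four screen metrics, per diagnostic group.

suppressMessages(library(screensca))

tbl <- readr::read_csv("results/analysis_table.csv", show_col_types = FALSE)
roster <- read_roster("results/inputs/roster.csv")

bl <- baseline_correlations(tbl, roster)
readr::write_csv(bl, "results/baseline_correlations.csv")
cat(sprintf("baseline screen: rho in [%.2f, %.2f]; %d of %d tests significant after FDR\n",
            min(bl$rho), max(bl$rho), sum(bl$p_fdr < 0.05), nrow(bl)))

fits <- lapply(c("SZ", "HC"), function(g) cognition_regression(tbl, g))
for (f in fits) print(f)
cog <- do.call(rbind, lapply(fits, function(f) {
  data.frame(group = f$group, n_obs = f$n_obs, F_stat = f$F_stat,
             df_num = f$df_num, df_den = f$df_den, p_overall = f$p_overall,
             adj_r2 = f$adj_r2)
}))
readr::write_csv(cog, "results/cognition_regression.csv")
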