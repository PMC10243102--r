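#!/usr/bin/env Rscript
# Univariate screening: per-metabolite Wilcoxon rank-sum tests for each
# stage-vs-control comparison, BH-adjusted within comparison, with
# case-over-control fold changes; the biomarker panel is the intersection
# of all six significant sets.  A descriptive monotone-trend screen looks
# for metabolites tracking disease progression across the stages.

library(oplsrisk)

profiles <- read_profiles("results/data/profiles_normalized.csv")

comparisons <- expand.grid(control = c("HC", "DM2"),
                           case = c("PC_I_II", "PC_III", "PC_IV"),
                           stringsAsFactors = FALSE)
tables <- lapply(seq_len(nrow(comparisons)), function(i)
  univariate_table(profiles, comparisons$control[i], comparisons$case[i]))
univ <- do.call(rbind, tables)
write.csv(univ, "results/univariate.csv", row.names = FALSE)

panel <- panel_overlap(tables, threshold = 0.05)
print(panel)
jsonlite::write_json(list(metabolites = panel$metabolites,
                          threshold = panel$threshold),
                     "results/panel.json", auto_unbox = TRUE, digits = NA)

trend <- stage_trend_screen(profiles)
cat("monotone stage trends found:", nrow(trend), "\n")
print(trend)
write.csv(trend, "results/stage_trends.csv", row.names = FALSE)
cat("written results/univariate.csv, results/panel.json, results/stage_trends.csv\n")
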