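#!/usr/bin/env Rscript
# ROC assessment of the biomarker panel found in step 04: a random-forest
# scorer under 100-cycle Monte-Carlo cross-validation, reporting the mean
# held-out AUC with a 95% percentile confidence interval for each
# stage-vs-control comparison.  An AUC above 0.8 marks the panel as
# clinically acceptable.

library(oplsrisk)

profiles <- read_profiles("results/data/profiles_normalized.csv")
panel <- jsonlite::fromJSON("results/panel.json")$metabolites
cat("panel of", length(panel), "metabolites\n")

comparisons <- expand.grid(control = c("HC", "DM2"),
                           case = c("PC_I_II", "PC_III", "PC_IV"),
                           stringsAsFactors = FALSE)
out <- list()
for (i in seq_len(nrow(comparisons))) {
  key <- paste(comparisons$control[i], "vs", comparisons$case[i])
  res <- panel_auc(profiles, panel, comparisons$control[i],
                   comparisons$case[i], n_repeats = 100, seed = 500 + i)
  cat(sprintf("%-16s AUC %.3f (95%% CI %.3f-%.3f)%s\n", key, res$auc,
              res$ci_lower, res$ci_upper,
              if (res$acceptable) " [acceptable]" else ""))
  out[[key]] <- list(auc = res$auc, ci_lower = res$ci_lower,
                     ci_upper = res$ci_upper, acceptable = res$acceptable)
}
jsonlite::write_json(out, "results/panel_roc.json", auto_unbox = TRUE,
                     digits = NA)
cat("written results/panel_roc.json\n")
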