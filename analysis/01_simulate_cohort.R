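#!/usr/bin/env Rscript
# Generate the study-scale synthetic cohort used by the downstream steps:
# six groups at the study's sample sizes (207 plasma profiles, 63 quantified
# metabolites including two contaminant signals), a 9-metabolite biomarker
# panel shifted 2-fold in every cancer group, 11 stage-trend metabolites,
# and a recent-onset-diabetes (RODM) cohort in which 20% of samples are
# latently cancer-like.  Ground truth is kept alongside for the recovery
# checks of step 06.

library(oplsrisk)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(effect_size = 2, rodm_pc_fraction = 0.2, seed = 101)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/data/cohort.csv")

cat("cohort:", nrow(cohort$profiles$values), "samples x",
    ncol(cohort$profiles$values), "metabolites\n")
print(truth_summary(cohort$truth)$by_group)
cat("latent composition of the RODM group:\n")
print(truth_summary(cohort$truth)$rodm_latent)
cat("written to results/data/cohort.csv (+ _truth.csv)\n")
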