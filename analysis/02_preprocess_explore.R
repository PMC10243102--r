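#!/usr/bin/env Rscript
# Preprocessing and unsupervised overview: drop the two contaminant
# signals (glycerol from the ultrafiltration membranes, propylene glycol
# from the environment), normalize each profile to total area to remove
# plasma-dilution differences, and inspect group structure by PCA.

library(oplsrisk)

cohort <- read_profiles("results/data/cohort.csv")
cat("loaded", nrow(cohort$values), "x", ncol(cohort$values), "\n")

profiles <- exclude_metabolites(cohort, c("Glycerol", "Propylene glycol"))
cat("after exclusion:", ncol(profiles$values), "metabolites\n")
profiles <- normalize_total_area(profiles)
stopifnot(all(abs(rowSums(profiles$values) - 1) < 1e-9))
write_profiles(profiles, "results/data/profiles_normalized.csv")

pca <- fit_pca(scale_profiles(profiles), k = 5)
cat("PCA explained variance (first 5 components):",
    sprintf("%.1f%%", 100 * pca$explained), "\n")
jsonlite::write_json(list(explained = pca$explained),
                     "results/pca_overview.json", digits = NA)
cat("written results/data/profiles_normalized.csv, results/pca_overview.json\n")
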