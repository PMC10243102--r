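#!/usr/bin/env Rscript
# Pairwise OPLS-DA of each cancer stage against both control groups, with
# the minimum component count maximizing cross-validated accuracy,
# 100-cycle Monte-Carlo cross-validation (90/10 stratified splits) and a
# label-permutation test.  200 permutations with a 20-cycle inner CV keep
# this step to about a minute; the permutation p-values of separable pairs
# are bounded, not refined, by the permutation count.

library(oplsrisk)

profiles <- read_profiles("results/data/profiles_normalized.csv")

comparisons <- expand.grid(control = c("HC", "DM2"),
                           case = c("PC_I_II", "PC_III", "PC_IV"),
                           stringsAsFactors = FALSE)
rows <- list()
for (i in seq_len(nrow(comparisons))) {
  ctrl <- comparisons$control[i]; case <- comparisons$case[i]
  sub <- subset_profiles(profiles, groups = c(ctrl, case))
  sel <- select_components(sub$values, sub$groups, max_total = 4,
                           n_iterations = 20, seed = 300 + i,
                           classes = c(ctrl, case))
  spec <- opls_spec(k_ortho = sel$k_ortho, classes = c(ctrl, case))
  cv <- monte_carlo_cv(sub$values, sub$groups, spec, n_iterations = 100,
                       seed = 310 + i, positive_class = case)
  perm <- permutation_test(sub$values, sub$groups, spec,
                           n_permutations = 200, n_cv_iterations = 20,
                           seed = 320 + i, positive_class = case)
  rows[[i]] <- data.frame(discrimination = paste(ctrl, "vs", case),
                          components = sel$n_components_total,
                          accuracy = round(cv$mean$accuracy, 1),
                          sensitivity = round(cv$mean$sensitivity, 1),
                          specificity = round(cv$mean$specificity, 1),
                          p_value = format_pvalue(perm$p_value, 200))
  cat(sprintf("%-16s %d comp  acc %5.1f  sens %5.1f  spec %5.1f  p %s\n",
              rows[[i]]$discrimination, rows[[i]]$components,
              rows[[i]]$accuracy, rows[[i]]$sensitivity,
              rows[[i]]$specificity, rows[[i]]$p_value))
}
perf <- do.call(rbind, rows)
write.csv(perf, "results/stage_discrimination.csv", row.names = FALSE)
cat("written results/stage_discrimination.csv\n")
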