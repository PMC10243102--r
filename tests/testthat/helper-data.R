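scale_values <- oplsrisk:::scale_values

# Reduced cohort for fast tests: same structure as the defaults, smaller n.
small_config <- function(...) {
  cohort_config(group_sizes = c(HC = 12, DM2 = 14, PC_I_II = 10,
                                PC_III = 10, PC_IV = 12, RODM = 20), ...)
}

# exclusion + total-area normalization, the fixed preprocessing order
preprocess <- function(profiles) {
  normalize_total_area(
    exclude_metabolites(profiles, c("Glycerol", "Propylene glycol")))
}

# Two well-separated Gaussian clusters (separation in units of the noise sd
# along the first variable).
two_clusters <- function(n_per = 10, m = 5, sep = 10, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * m), 2 * n_per, m,
              dimnames = list(sprintf("s%02d", seq_len(2 * n_per)),
                              paste0("v", seq_len(m))))
  x[seq_len(n_per), 1] <- x[seq_len(n_per), 1] + sep
  list(x = x, y = rep(c("A", "B"), each = n_per))
}

# Vote counts of the reference worked example shipped with the package.
reference_votes <- function() {
  read.csv(system.file("extdata", "reference_vote_counts.csv",
                       package = "oplsrisk"), check.names = FALSE)
}

reference_pvalues <- function() {
  read.csv(system.file("extdata", "reference_panel_pvalues.csv",
                       package = "oplsrisk"), check.names = FALSE)
}
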