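#' Configuration for a synthetic plasma metabolomics cohort
#'
#' Defines the statistical structure the downstream analysis assumes: six
#' study groups (healthy controls, type-2 diabetics, three pancreatic-cancer
#' stage groups, and a recent-onset-diabetes cohort that is a latent mixture
#' of DM2-like and PC-like samples), a biomarker panel whose metabolites are
#' shifted in every PC group, and trend metabolites whose means change
#' monotonically with cancer stage.
#'
#' Concentrations are log-normal: each value is drawn around its
#' group-specific mean with coefficient of variation `noise_cv`.  Panel
#' metabolites have their mean multiplied by `effect_size` in all PC groups
#' (and in PC-like RODM samples).  Trend metabolite means follow a geometric
#' progression across PC I+II, III, IV with per-stage step
#' `sqrt(effect_size)` (upward or downward), so `effect_size = 1` makes all
#' groups exchangeable — the null configuration used for calibration tests.
#'
#' Two contaminant columns, `"Glycerol"` and `"Propylene glycol"`, are
#' always generated so the exclusion filter is exercised end-to-end.
#'
#' @param group_sizes named integer vector of samples per group.
#' @param n_metabolites total metabolite count before exclusion (>= panel +
#'   trend + 2 contaminants).
#' @param panel_metabolites metabolites carrying the PC-vs-control effect.
#' @param trend_up,trend_down metabolites with monotonically increasing /
#'   decreasing stage means.
#' @param effect_size multiplicative mean shift (> 0, dimensionless).
#' @param noise_cv coefficient of variation of the log-normal noise.
#' @param rodm_pc_fraction fraction of RODM samples drawn from the PC-like
#'   distribution (count = `round(fraction * n_RODM)`).
#' @param latent_rank rank of an optional shared log-scale latent factor
#'   inducing metabolite-metabolite correlation; 0 (default) = independent
#'   metabolites.
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(HC = 28, DM2 = 32, PC_I_II = 26,
                                          PC_III = 27, PC_IV = 35, RODM = 59),
                          n_metabolites = 63,
                          panel_metabolites = c("3-hydroxyisovalerate",
                                                "creatine", "fumarate",
                                                "gluconate", "lysine",
                                                "mannose", "N-acetylcysteine",
                                                "proline", "propionate"),
                          trend_up = c("hydroxyacetone",
                                       "2-hydroxyisovalerate",
                                       "3-methyl-2-oxovalerate"),
                          trend_down = c("alanine", "creatinine",
                                         "dimethylamine",
                                         "N,N-dimethylglycine", "ethanol",
                                         "formate", "hypoxanthine", "valine"),
                          effect_size = 1.5,
                          noise_cv = 0.3,
                          rodm_pc_fraction = 0.2,
                          latent_rank = 0,
                          seed = 1L) {
  if (is.null(names(group_sizes)) || any(names(group_sizes) == ""))
    stop("invalid `group_sizes`: must be a named vector", call. = FALSE)
  if (any(group_sizes < 2))
    stop("invalid `group_sizes`: all group sizes must be >= 2", call. = FALSE)
  if (!is.numeric(effect_size) || length(effect_size) != 1L || effect_size <= 0)
    stop("invalid `effect_size`: must be a single positive number", call. = FALSE)
  if (!is.numeric(noise_cv) || noise_cv <= 0)
    stop("invalid `noise_cv`: must be positive", call. = FALSE)
  if (rodm_pc_fraction < 0 || rodm_pc_fraction > 1)
    stop("invalid `rodm_pc_fraction`: must be in [0, 1]", call. = FALSE)
  special <- c(panel_metabolites, trend_up, trend_down)
  if (anyDuplicated(special))
    stop("invalid metabolite lists: panel, trend_up and trend_down must be disjoint",
         call. = FALSE)
  if (n_metabolites < length(special) + 2L)
    stop("invalid `n_metabolites`: too small for panel + trend + 2 contaminants",
         call. = FALSE)
  if (latent_rank < 0)
    stop("invalid `latent_rank`: must be >= 0", call. = FALSE)
  structure(list(group_sizes = group_sizes, n_metabolites = n_metabolites,
                 panel_metabolites = panel_metabolites, trend_up = trend_up,
                 trend_down = trend_down, effect_size = effect_size,
                 noise_cv = noise_cv, rodm_pc_fraction = rodm_pc_fraction,
                 latent_rank = latent_rank, seed = as.integer(seed)),
            class = "cohort_config")
}

# Filler names: common plasma NMR metabolites without planted effects.
filler_metabolites <- c(
  "glucose", "lactate", "citrate", "acetate", "acetone", "acetoacetate",
  "3-hydroxybutyrate", "pyruvate", "succinate", "glutamate", "glutamine",
  "glycine", "histidine", "isoleucine", "leucine", "phenylalanine",
  "tyrosine", "threonine", "methionine", "ornithine", "arginine",
  "asparagine", "betaine", "carnitine", "choline", "sarcosine", "serine",
  "taurine", "tryptophan", "urea", "myo-inositol", "malonate", "methanol",
  "isopropanol", "citrulline", "glycerate", "2-oxoglutarate",
  "acetylcarnitine", "3-methylhistidine", "trimethylamine N-oxide")

cohort_metabolite_names <- function(config) {
  special <- c(config$panel_metabolites, config$trend_up, config$trend_down)
  n_fill <- config$n_metabolites - length(special) - 2L
  fill <- setdiff(filler_metabolites, special)
  if (n_fill > length(fill))
    fill <- c(fill, sprintf("metabolite_%03d", seq_len(n_fill - length(fill))))
  c(special, fill[seq_len(n_fill)], "Glycerol", "Propylene glycol")
}

#' Generate a synthetic cohort
#'
#' Draws a seeded cohort from the model described in [cohort_config()] and
#' returns both the raw (unnormalized) concentration table and the ground
#' truth of how each sample was generated, so recovery tests can score the
#' downstream analysis.
#'
#' RODM samples are a labeled mixture: `round(rodm_pc_fraction * n_RODM)`
#' samples are drawn from a PC-stage distribution (the stage cycling through
#' PC I+II, III, IV), the rest from the DM2 distribution.  The `group` label
#' of all of them is `"RODM"`; the generating distribution is recorded in
#' the truth labels only.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `profiles` (a [profile_matrix()], strictly
#'   positive, unnormalized) and `truth` (data frame `sample_id`, `group`,
#'   `latent_group` giving the generating distribution of every sample).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  mets <- cohort_metabolite_names(config)
  m <- length(mets)
  # per-metabolite baseline concentrations (arbitrary units), spread over
  # ~2 orders of magnitude as plasma profiles are
  base <- exp(stats::rnorm(m, mean = log(50), sd = 1))
  names(base) <- mets

  step <- sqrt(config$effect_size)
  stage_of <- c(PC_I_II = 0, PC_III = 1, PC_IV = 2)
  # multiplicative group effect on the mean of metabolite `met` for a sample
  # generated from distribution `dist` (a group name)
  effect_for <- function(dist) {
    f <- rep(1, m)
    names(f) <- mets
    if (dist %in% names(stage_of)) {
      f[config$panel_metabolites] <- config$effect_size
      f[config$trend_up] <- step^stage_of[[dist]]
      f[config$trend_down] <- step^(-stage_of[[dist]])
    }
    f
  }

  sizes <- config$group_sizes
  groups <- rep(names(sizes), times = sizes)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))

  latent <- groups
  if ("RODM" %in% names(sizes)) {
    idx <- which(groups == "RODM")
    latent[idx] <- "DM2"
    n_pc <- round(config$rodm_pc_fraction * length(idx))
    if (n_pc > 0) {
      pc_idx <- sample(idx, n_pc)
      latent[pc_idx] <- rep(c("PC_I_II", "PC_III", "PC_IV"),
                            length.out = n_pc)
    }
  }

  sigma <- sqrt(log(1 + config$noise_cv^2))
  vals <- matrix(0, n, m, dimnames = list(ids, mets))
  lambda <- NULL
  if (config$latent_rank > 0)
    lambda <- matrix(stats::rnorm(m * config$latent_rank, sd = 0.1),
                     config$latent_rank, m)
  for (i in seq_len(n)) {
    mu <- base * effect_for(latent[i])
    # -sigma^2/2 keeps E[value] equal to mu exactly
    logv <- log(mu) + stats::rnorm(m, 0, sigma) - sigma^2 / 2
    if (!is.null(lambda))
      logv <- logv + drop(stats::rnorm(config$latent_rank) %*% lambda)
    vals[i, ] <- exp(logv)
  }

  list(profiles = profile_matrix(vals, groups),
       truth = data.frame(sample_id = ids, group = groups,
                          latent_group = latent,
                          stringsAsFactors = FALSE))
}

#' Summarize ground-truth labels
#'
#' @param truth the `truth` data frame from [generate_cohort()].
#' @return A list with `n_total`, `by_group` (counts per declared group) and
#'   `rodm_latent` (counts of RODM samples per generating distribution).
#' @export
truth_summary <- function(truth) {
  if (nrow(truth) == 0L) stop("empty truth labels", call. = FALSE)
  rodm <- truth[truth$group == "RODM", , drop = FALSE]
  list(n_total = nrow(truth),
       by_group = table(truth$group),
       rodm_latent = if (nrow(rodm)) table(rodm$latent_group) else table(character()))
}

#' Write a cohort to disk
#'
#' Writes the profile matrix as a CSV (see [write_profiles()]) and the truth
#' labels as a sidecar CSV next to it.
#'
#' @param cohort result of [generate_cohort()].
#' @param path path for the profile CSV; the truth table is written to
#'   `<path minus .csv>_truth.csv`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write_profiles(cohort$profiles, path)
  truth_path <- sub("\\.csv$", "", path)
  utils::write.csv(cohort$truth, paste0(truth_path, "_truth.csv"),
                   row.names = FALSE)
  invisible(path)
}
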