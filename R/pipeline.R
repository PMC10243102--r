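default_run_config <- function() {
  list(version = 1,
       input = NULL,
       synthetic = list(),
       exclude_list = c("Glycerol", "Propylene glycol"),
       scaling_method = "unit_variance",
       control_groups = c("HC", "DM2"),
       stage_groups = c("PC_I_II", "PC_III", "PC_IV"),
       external_group = "RODM",
       panel_threshold = 0.05,
       validation = list(n_cv = 100L, n_perm = 1000L, perm_cv = 20L,
                         max_components = 5L),
       ensemble = list(n_models = 20L, min_accuracy = 80,
                       subsample_size = 25L, k_ortho = 1L),
       roc = list(n_repeats = 100L, classifier = "random-forest"),
       out_dir = "results/run",
       seed = 1L)
}

#' Load and validate a study configuration
#'
#' Accepts a YAML file path or a list.  Keys override the defaults of
#' `default_run_config`; unknown keys (at the top level or inside nested
#' sections) are errors, not warnings.
#'
#' @param config path to a YAML file, or a (possibly partial) list.
#' @return The merged, validated configuration list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (section in c("validation", "ensemble", "roc")) {
    if (!is.null(config[[section]])) {
      bad <- setdiff(names(config[[section]]), names(defaults[[section]]))
      if (length(bad))
        stop("unknown config key(s) in ", section, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
      defaults[[section]][names(config[[section]])] <- config[[section]]
      config[[section]] <- NULL
    }
  }
  defaults[names(config)] <- config
  defaults
}

#' Run the complete study workflow
#'
#' Orchestrates the full analysis flow: cohort input (file or seeded
#' synthetic generation), exclusion filtering and total-area normalization,
#' PCA overview, per-comparison OPLS-DA with component selection,
#' Monte-Carlo cross-validation and permutation testing, univariate
#' screening with biomarker-panel construction, panel ROC assessment, and
#' external risk classification.  All artifacts are written under
#' `config$out_dir`; identical configurations (including the seed) give
#' identical outputs.
#'
#' @param config a [run_config()] input (list or YAML path).
#' @return The output directory, invisibly.  Artifacts:
#'   `performance.csv`, `univariate.csv`, `panel.json`, `roc.json`,
#'   `risk_votes.csv`, `risk.json`, `pca.json`, `summary.md`.
#' @export
run_study <- function(config = list()) {
  cfg <- run_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # --- input stage -----------------------------------------------------
  if (!is.null(cfg$input)) {
    profiles <- read_profiles(cfg$input)
  } else {
    cc <- do.call(cohort_config, c(cfg$synthetic,
                                   if (is.null(cfg$synthetic$seed))
                                     list(seed = cfg$seed)))
    profiles <- generate_cohort(cc)$profiles
  }
  need <- c(cfg$control_groups, cfg$stage_groups, cfg$external_group)
  missing <- setdiff(need, unique(profiles$groups))
  if (length(missing))
    stop("input stage: group(s) not present in data: ",
         paste(missing, collapse = ", "), call. = FALSE)

  # --- preprocessing ---------------------------------------------------
  profiles <- exclude_metabolites(profiles,
                                  intersect(cfg$exclude_list,
                                            colnames(profiles$values)))
  profiles <- normalize_total_area(profiles)

  # --- PCA overview ----------------------------------------------------
  pca <- fit_pca(scale_profiles(profiles, cfg$scaling_method), k = 2L)
  jsonlite::write_json(list(explained = pca$explained),
                       file.path(out, "pca.json"), digits = NA)

  comparisons <- expand.grid(control = cfg$control_groups,
                             case = cfg$stage_groups,
                             stringsAsFactors = FALSE)

  # --- discrimination + validation ------------------------------------
  perf_rows <- list()
  for (i in seq_len(nrow(comparisons))) {
    ctrl <- comparisons$control[i]; case <- comparisons$case[i]
    sub <- subset_profiles(profiles, groups = c(ctrl, case))
    sel <- select_components(sub$values, sub$groups,
                             max_total = cfg$validation$max_components,
                             n_iterations = cfg$validation$perm_cv,
                             seed = cfg$seed + i,
                             scaling = cfg$scaling_method,
                             classes = c(ctrl, case))
    spec <- opls_spec(k_ortho = sel$k_ortho, scaling = cfg$scaling_method,
                      classes = c(ctrl, case))
    cv <- monte_carlo_cv(sub$values, sub$groups, spec,
                         n_iterations = cfg$validation$n_cv,
                         seed = cfg$seed + 10L + i, positive_class = case)
    perm <- permutation_test(sub$values, sub$groups, spec,
                             n_permutations = cfg$validation$n_perm,
                             n_cv_iterations = cfg$validation$perm_cv,
                             seed = cfg$seed + 20L + i,
                             positive_class = case)
    perf_rows[[i]] <- data.frame(
      discrimination = paste(ctrl, "vs", case),
      components = sel$n_components_total,
      accuracy = cv$mean$accuracy, sensitivity = cv$mean$sensitivity,
      specificity = cv$mean$specificity, p_value = perm$p_value,
      p_formatted = format_pvalue(perm$p_value, perm$n_permutations),
      stringsAsFactors = FALSE)
  }
  perf <- do.call(rbind, perf_rows)
  utils::write.csv(perf, file.path(out, "performance.csv"), row.names = FALSE)

  # --- univariate + panel ---------------------------------------------
  tables <- lapply(seq_len(nrow(comparisons)), function(i)
    univariate_table(profiles, comparisons$control[i], comparisons$case[i]))
  univ <- do.call(rbind, tables)
  utils::write.csv(univ, file.path(out, "univariate.csv"), row.names = FALSE)
  panel <- panel_overlap(tables, threshold = cfg$panel_threshold)
  jsonlite::write_json(list(metabolites = panel$metabolites,
                            threshold = panel$threshold,
                            comparisons = panel$comparisons),
                       file.path(out, "panel.json"), digits = NA)

  # --- panel ROC -------------------------------------------------------
  roc_out <- list()
  if (length(panel$metabolites)) {
    scorer <- if (identical(cfg$roc$classifier, "linear")) linear_score_spec()
              else rf_score_spec()
    for (i in seq_len(nrow(comparisons))) {
      key <- paste(comparisons$control[i], "vs", comparisons$case[i])
      pr <- panel_auc(profiles, panel$metabolites, comparisons$control[i],
                      comparisons$case[i], n_repeats = cfg$roc$n_repeats,
                      seed = cfg$seed + 30L + i, scorer = scorer)
      roc_out[[key]] <- list(auc = pr$auc, ci_lower = pr$ci_lower,
                             ci_upper = pr$ci_upper,
                             acceptable = pr$acceptable)
    }
  }
  jsonlite::write_json(roc_out, file.path(out, "roc.json"), digits = NA,
                       auto_unbox = TRUE)

  # --- risk classification --------------------------------------------
  risk <- predict_risk(profiles, control = cfg$control_groups[2],
                       stages = cfg$stage_groups,
                       external = cfg$external_group,
                       n_models = cfg$ensemble$n_models,
                       min_accuracy = cfg$ensemble$min_accuracy,
                       external_subsample_size = cfg$ensemble$subsample_size,
                       k_ortho = cfg$ensemble$k_ortho,
                       seed = cfg$seed + 40L)
  votes <- data.frame(sample = risk$records[[1]]$sample,
                      stringsAsFactors = FALSE)
  for (nm in names(risk$records)) {
    votes[[paste0(nm, "_ratio")]] <-
      format_ratio(risk$records[[nm]]$votes, risk$records[[nm]]$applications)
  }
  votes$stage_label <- unname(
    stage_majority_labels(risk$stage_records)[votes$sample])
  utils::write.csv(votes, file.path(out, "risk_votes.csv"), row.names = FALSE)
  risk_json <- list(at_risk = risk$at_risk,
                    selected = lapply(risk$selected, identity),
                    n_models_total = risk$n_models_total)
  if (!is.null(risk$stage_assignment))
    risk_json$agreement <- risk$stage_assignment$agreement
  jsonlite::write_json(risk_json, file.path(out, "risk.json"), digits = NA,
                       auto_unbox = TRUE)

  render_reports(out)
  invisible(out)
}

#' Render a human-readable study summary
#'
#' Collects the artifacts of a [run_study()] directory into `summary.md`:
#' the performance table with permutation p-values (values below the test
#' resolution shown as a bound, e.g. `<0.001`), the biomarker panel, panel
#' AUCs, and the risk-classification table with ratios to one decimal.
#'
#' @param dir a run directory produced by [run_study()].
#' @return Path of the summary file, invisibly.
#' @export
render_reports <- function(dir) {
  need <- c("performance.csv", "panel.json", "roc.json", "risk_votes.csv",
            "risk.json")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("missing artifact: ", f, call. = FALSE)
  perf <- utils::read.csv(file.path(dir, "performance.csv"),
                          check.names = FALSE)
  panel <- jsonlite::fromJSON(file.path(dir, "panel.json"))
  roc <- jsonlite::fromJSON(file.path(dir, "roc.json"))
  votes <- utils::read.csv(file.path(dir, "risk_votes.csv"),
                           check.names = FALSE)
  risk <- jsonlite::fromJSON(file.path(dir, "risk.json"))

  lines <- c("# Study summary", "", "## Discrimination performance", "",
             paste("|", paste(c("discrimination", "components", "accuracy %",
                                "sensitivity %", "specificity %", "P-value"),
                              collapse = " | "), "|"),
             paste("|", paste(rep("---", 6), collapse = " | "), "|"))
  for (i in seq_len(nrow(perf)))
    lines <- c(lines, sprintf("| %s | %d | %.1f | %.1f | %.1f | %s |",
                              perf$discrimination[i], perf$components[i],
                              perf$accuracy[i], perf$sensitivity[i],
                              perf$specificity[i], perf$p_formatted[i]))
  lines <- c(lines, "", "## Biomarker panel", "",
             sprintf("%d metabolite(s) significant in every comparison (adjusted p < %g):",
                     length(panel$metabolites), panel$threshold),
             if (length(panel$metabolites))
               paste0("- ", panel$metabolites) else "- none")
  lines <- c(lines, "", "## Panel ROC", "")
  if (length(roc)) {
    for (nm in names(roc))
      lines <- c(lines, sprintf("- %s: AUC %.3f (95%% CI %.3f-%.3f)%s", nm,
                                roc[[nm]]$auc, roc[[nm]]$ci_lower,
                                roc[[nm]]$ci_upper,
                                if (isTRUE(roc[[nm]]$acceptable))
                                  " [acceptable]" else ""))
  } else lines <- c(lines, "- no panel to assess")
  lines <- c(lines, "", "## External risk classification", "")
  if (length(risk$at_risk)) {
    shown <- votes[votes$sample %in% risk$at_risk, , drop = FALSE]
    lines <- c(lines,
               paste("|", paste(names(shown), collapse = " | "), "|"),
               paste("|", paste(rep("---", ncol(shown)), collapse = " | "), "|"))
    for (i in seq_len(nrow(shown)))
      lines <- c(lines, paste("|", paste(unlist(shown[i, ]), collapse = " | "), "|"))
    if (!is.null(risk$agreement))
      lines <- c(lines, "",
                 sprintf("Early/late agreement between assignment sources: %.1f%%",
                         risk$agreement))
  } else {
    lines <- c(lines, "none selected")
  }
  path <- file.path(dir, "summary.md")
  writeLines(lines, path)
  invisible(path)
}
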