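#' Two-group Wilcoxon rank-sum test
#'
#' Two-sided rank-sum p-value, the nonparametric default for metabolite
#' concentrations (which are right-skewed, not normal).  `mode = "exact"`
#' enumerates the exact null distribution and refuses ties; `"approx"` uses
#' the normal approximation with midranks and tie-corrected variance;
#' `"auto"` (default) picks exact when both groups have at most
#' `exact_threshold` values and there are no ties.
#'
#' @param a,b numeric vectors (each nonempty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param exact_threshold group-size limit for automatic exact enumeration.
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "approx"),
                              exact_threshold = 50L) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  if (mode == "exact" && ties)
    stop("exact mode is not defined in the presence of ties", call. = FALSE)
  exact <- switch(mode,
                  exact = TRUE,
                  approx = FALSE,
                  auto = !ties && length(a) <= exact_threshold &&
                    length(b) <= exact_threshold)
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = !exact))
  unname(res$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction of a family of p-values; the
#' family is one comparison's full metabolite list.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return Adjusted p-values, elementwise >= input, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Fold change between group means
#'
#' Ratio of arithmetic group means, oriented case over control:
#' `mean(case) / mean(control)`, so values above 1 mean the metabolite is
#' elevated in the case group.
#'
#' @param control,case numeric vectors with positive means.
#' @return The ratio (dimensionless).
#' @export
fold_change <- function(control, case) {
  mc <- mean(control); mk <- mean(case)
  if (mc <= 0 || mk <= 0)
    stop("fold change requires positive group means", call. = FALSE)
  mk / mc
}

#' Per-metabolite univariate screen for one comparison
#'
#' Wilcoxon rank-sum p-values for every metabolite, BH-adjusted within the
#' comparison, with case-over-control fold changes.
#'
#' @param m a `profile_matrix` containing both groups.
#' @param control,case group labels (control first; fold change and
#'   direction are case relative to control).
#' @param mode passed to [wilcoxon_rank_sum()].
#' @return A data frame of class `univariate_table` with columns
#'   `metabolite`, `comparison`, `p_raw`, `p_adj`, `fold_change`,
#'   `direction` (+1 elevated in case, -1 decreased, 0 equal).
#' @export
univariate_table <- function(m, control, case, mode = "auto") {
  stopifnot(inherits(m, "profile_matrix"))
  for (g in c(control, case))
    if (!g %in% m$groups) stop("unknown group: ", g, call. = FALSE)
  a <- m$values[m$groups == control, , drop = FALSE]
  b <- m$values[m$groups == case, , drop = FALSE]
  p_raw <- vapply(seq_len(ncol(a)), function(j)
    wilcoxon_rank_sum(a[, j], b[, j], mode = mode), numeric(1))
  fc <- vapply(seq_len(ncol(a)), function(j)
    fold_change(a[, j], b[, j]), numeric(1))
  out <- data.frame(metabolite = colnames(a),
                    comparison = paste(control, "vs", case),
                    p_raw = p_raw,
                    p_adj = bh_adjust(p_raw),
                    fold_change = fc,
                    direction = sign(fc - 1),
                    stringsAsFactors = FALSE)
  class(out) <- c("univariate_table", "data.frame")
  out
}

#' Cross-comparison biomarker panel
#'
#' Intersects the significant metabolite sets of several comparisons: a
#' metabolite enters the panel only if its adjusted p-value is below the
#' threshold in every comparison.
#'
#' @param tables list of `univariate_table` data frames (or any data frames
#'   with `metabolite` and `p_adj` columns) sharing one metabolite universe.
#' @param threshold significance threshold on adjusted p-values.
#' @return A list of class `biomarker_panel`: `metabolites` (the panel, in
#'   the order of the first table), `comparisons`, `threshold`.
#' @export
panel_overlap <- function(tables, threshold = 0.05) {
  if (!length(tables)) stop("no tables given", call. = FALSE)
  universe <- sort(tables[[1]]$metabolite)
  panel <- tables[[1]]$metabolite
  for (tab in tables) {
    if (!identical(sort(tab$metabolite), universe))
      stop("tables do not share one metabolite universe", call. = FALSE)
    sig <- tab$metabolite[tab$p_adj < threshold]
    panel <- panel[panel %in% sig]
  }
  comparisons <- vapply(tables, function(tab)
    if ("comparison" %in% names(tab)) tab$comparison[1] else NA_character_,
    character(1))
  structure(list(metabolites = panel, comparisons = comparisons,
                 threshold = threshold),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("<biomarker_panel> %d metabolite(s) significant in all %d comparison(s) at adjusted p < %g:\n",
              length(x$metabolites), length(x$comparisons), x$threshold))
  cat(" ", paste(x$metabolites, collapse = ", "), "\n")
  invisible(x)
}

#' Screen for stage-graded metabolite trends
#'
#' Descriptive screen (no test): reports metabolites whose group mean
#' concentrations are strictly monotone across the ordered stage groups —
#' the pattern of disease-progression markers.
#'
#' @param m a `profile_matrix`.
#' @param stages ordered vector of >= 3 stage group labels.
#' @return A data frame with columns `metabolite`, `direction` (`"up"` or
#'   `"down"`) for each strictly monotone metabolite, plus the per-stage
#'   means as attribute `stage_means`.
#' @export
stage_trend_screen <- function(m, stages = c("PC_I_II", "PC_III", "PC_IV")) {
  stopifnot(inherits(m, "profile_matrix"))
  if (length(stages) < 3L) stop("need >= 3 stage groups", call. = FALSE)
  for (g in stages)
    if (!g %in% m$groups) stop("unknown group: ", g, call. = FALSE)
  means <- t(vapply(stages, function(g)
    colMeans(m$values[m$groups == g, , drop = FALSE]),
    numeric(ncol(m$values))))
  up <- apply(means, 2L, function(v) all(diff(v) > 0))
  down <- apply(means, 2L, function(v) all(diff(v) < 0))
  out <- data.frame(metabolite = colnames(m$values)[up | down],
                    direction = ifelse(up[up | down], "up", "down"),
                    stringsAsFactors = FALSE)
  attr(out, "stage_means") <- means
  out
}
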