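#' ROC curve and AUC from continuous scores
#'
#' The AUC equals the Mann-Whitney concordance probability: the chance a
#' random positive sample outscores a random negative one, ties counted
#' one half.  Curve construction and integration are delegated to pROC.
#'
#' @param scores numeric vector (higher = more positive).
#' @param labels two-class label vector.
#' @param positive_class label treated as positive (default: alphabetically
#'   second class).
#' @return A list of class `roc_result`: `auc`, and `curve` (data frame
#'   `fpr`, `tpr`).
#' @export
roc_curve <- function(scores, labels, positive_class = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("exactly two classes required", call. = FALSE)
  if (is.null(positive_class)) positive_class <- classes[2L]
  r <- pROC::roc(response = labels == positive_class, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  structure(list(auc = as.numeric(pROC::auc(r)),
                 curve = data.frame(fpr = 1 - r$specificities,
                                    tpr = r$sensitivities)),
            class = "roc_result")
}

#' Random-forest scoring specification
#'
#' Score = the forest's class-probability vote for the positive class.
#' Seeded externally by the caller, so repeats are reproducible.
#'
#' @param ntree number of trees.
#' @return A list with `fit(x, y, positive_class)` and `score(model, x)`.
#' @export
rf_score_spec <- function(ntree = 500L) {
  list(fit = function(x, y, positive_class) {
         fit <- randomForest::randomForest(x, factor(y), ntree = ntree)
         list(fit = fit, positive_class = positive_class)
       },
       score = function(model, x)
         stats::predict(model$fit, x, type = "prob")[, model$positive_class],
       tag = "random-forest")
}

#' Linear discriminant scoring specification
#'
#' A deterministic fallback scorer: the autoscaled class-mean-difference
#' direction (a diagonal-covariance linear discriminant).  Useful for fast
#' exact tests of the ROC machinery.
#'
#' @return A fit/score specification as in [rf_score_spec()].
#' @export
linear_score_spec <- function() {
  list(fit = function(x, y, positive_class) {
         s <- scale_values(x, "unit_variance")
         w <- colMeans(s$values[y == positive_class, , drop = FALSE]) -
           colMeans(s$values[y != positive_class, , drop = FALSE])
         list(w = w, center = s$center, scale = s$scale)
       },
       score = function(model, x) {
         X <- sweep(sweep(x, 2L, model$center, "-"), 2L, model$scale, "/")
         drop(X %*% model$w)
       },
       tag = "linear")
}

#' Cross-validated panel AUC with confidence interval
#'
#' Assesses a biomarker panel by Monte-Carlo cross-validation of a scoring
#' classifier (random forest by default) restricted to the panel
#' metabolites.  Each repeat draws a stratified train/test split, fits the
#' scorer on the training part and computes the held-out AUC; the reported
#' AUC is the mean over repeats (`mode = "averaged"`) or the AUC of all
#' pooled held-out scores (`mode = "pooled"`), and the 95% confidence
#' interval is the 2.5/97.5 percentile range of the per-repeat AUCs.  A
#' panel with AUC above 0.8 is flagged acceptable, the conventional
#' biomarker-utility bound.
#'
#' @param m a `profile_matrix` containing both groups.
#' @param panel metabolite names to use (nonempty).
#' @param control,case the two group labels (case = positive class).
#' @param n_repeats cross-validation repeats (default 100).
#' @param train_fraction training fraction per repeat.
#' @param seed integer seed.
#' @param scorer scoring spec, default [rf_score_spec()].
#' @param mode `"averaged"` or `"pooled"`.
#' @return A list of class `roc_panel_result`: `auc`, `ci_lower`,
#'   `ci_upper`, `per_repeat_auc`, `acceptable`, `panel`, `mode`,
#'   `classifier`.
#' @export
panel_auc <- function(m, panel, control, case, n_repeats = 100L,
                      train_fraction = 0.9, seed = 1L,
                      scorer = rf_score_spec(), mode = c("averaged", "pooled")) {
  stopifnot(inherits(m, "profile_matrix"))
  mode <- match.arg(mode)
  if (!length(panel)) stop("empty panel", call. = FALSE)
  sub <- subset_profiles(m, groups = c(control, case), metabolites = panel)
  x <- sub$values
  y <- sub$groups
  if (sum(y == control) < 5L || sum(y == case) < 5L)
    stop("both classes need >= 5 samples", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  per_repeat <- numeric(n_repeats)
  pooled_scores <- numeric(0); pooled_labels <- character(0)
  for (r in seq_len(n_repeats)) {
    tr <- stratified_train_indices(y, train_fraction)
    te <- setdiff(seq_along(y), tr)
    model <- scorer$fit(x[tr, , drop = FALSE], y[tr], case)
    sc <- scorer$score(model, x[te, , drop = FALSE])
    per_repeat[r] <- roc_curve(sc, y[te], positive_class = case)$auc
    pooled_scores <- c(pooled_scores, sc)
    pooled_labels <- c(pooled_labels, y[te])
  }
  auc <- if (mode == "averaged") mean(per_repeat)
         else roc_curve(pooled_scores, pooled_labels, positive_class = case)$auc
  ci <- stats::quantile(per_repeat, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(auc = auc, ci_lower = ci[1], ci_upper = ci[2],
                 per_repeat_auc = per_repeat, acceptable = auc > 0.8,
                 panel = panel, n_repeats = n_repeats, mode = mode,
                 classifier = if (is.null(scorer$tag)) "custom" else scorer$tag,
                 seed = seed),
            class = "roc_panel_result")
}

#' @export
print.roc_panel_result <- function(x, ...) {
  cat(sprintf("<roc_panel_result> %d-metabolite panel: AUC %.3f (95%% CI %.3f-%.3f, %s over %d repeats)%s\n",
              length(x$panel), x$auc, x$ci_lower, x$ci_upper, x$mode,
              x$n_repeats, if (x$acceptable) " [acceptable]" else ""))
  invisible(x)
}
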