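#' Classification performance metrics
#'
#' Accuracy, sensitivity and specificity (percentages) with the underlying
#' confusion counts.  Sensitivity tracks the positive class (in the study
#' design, the pancreatic-cancer group of each comparison).
#'
#' @param truth,predicted label vectors of equal length.
#' @param positive_class the label counted as positive.
#' @return A list of class `performance`: `accuracy`, `sensitivity`,
#'   `specificity` (percent), and counts `tp`, `tn`, `fp`, `fn`.
#' @export
evaluate_performance <- function(truth, predicted, positive_class) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  if (!positive_class %in% truth)
    stop("unknown positive class: ", positive_class, call. = FALSE)
  pos <- truth == positive_class
  ppos <- predicted == positive_class
  tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
  tn <- sum(!pos & !ppos); fp <- sum(!pos & ppos)
  structure(list(accuracy = 100 * (tp + tn) / length(truth),
                 sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
                 tp = tp, tn = tn, fp = fp, fn = fn),
            class = "performance")
}

#' @export
print.performance <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

# Stratified train indices: round(train_fraction * n_c) per class, clipped
# so every class keeps >= 2 training and >= 1 test sample.
stratified_train_indices <- function(y, train_fraction) {
  idx <- integer(0)
  for (cl in unique(y)) {
    members <- which(y == cl)
    n_c <- length(members)
    n_train <- round(train_fraction * n_c)
    n_train <- max(2L, min(n_c - 1L, n_train))
    if (n_c < 3L)
      stop("class '", cl, "' too small to stratify (need >= 3 samples)",
           call. = FALSE)
    idx <- c(idx, sample(members, n_train))
  }
  sort(idx)
}

#' OPLS-DA model specification for cross-validation
#'
#' Packages fitting and prediction (including the scaling step, which is
#' re-estimated inside every training fold) behind the two-function
#' interface [monte_carlo_cv()] consumes.
#'
#' @param k_ortho orthogonal components.
#' @param scaling scaling method (see [scale_profiles()]).
#' @param classes optional fixed class order (second entry = coded 1).
#' @return A list with functions `fit(x, y)` and `predict(model, x)`.
#' @export
opls_spec <- function(k_ortho = 0L, scaling = "unit_variance",
                      classes = NULL) {
  list(fit = function(x, y) fit_oplsda(scale_values(x, scaling), y,
                                       k_ortho = k_ortho, classes = classes),
       predict = function(model, x) predict(model, x, type = "class"))
}

#' Nearest-centroid model specification
#'
#' A fast deterministic baseline classifier (autoscaled nearest class
#' centroid, Euclidean distance).  Used where many thousands of fits are
#' needed, e.g. the permutation-test calibration suite.
#'
#' @return A fit/predict specification as in [opls_spec()].
#' @export
centroid_spec <- function() {
  list(fit = function(x, y) {
         s <- scale_values(x, "unit_variance")
         cls <- sort(unique(as.character(y)))
         centroids <- t(vapply(cls, function(cl)
           colMeans(s$values[y == cl, , drop = FALSE]), numeric(ncol(x))))
         list(centroids = centroids, classes = cls,
              center = s$center, scale = s$scale)
       },
       predict = function(model, x) {
         X <- sweep(sweep(x, 2L, model$center, "-"), 2L, model$scale, "/")
         d <- vapply(seq_len(nrow(model$centroids)), function(i)
           rowSums(sweep(X, 2L, model$centroids[i, ], "-")^2),
           numeric(nrow(X)))
         model$classes[max.col(-d, ties.method = "first")]
       })
}

#' Monte-Carlo cross-validation
#'
#' Repeated random stratified train/test splitting: at each iteration a
#' fraction of every class (default 90%) trains the model and the held-out
#' remainder is scored.  Performance is averaged arithmetically over
#' iterations.
#'
#' @param x raw numeric matrix (samples x metabolites).
#' @param y two-class label vector.
#' @param model_spec a fit/predict list such as [opls_spec()].
#' @param n_iterations number of random splits (default 100).
#' @param train_fraction fraction of each class used for training.
#' @param seed integer seed; identical seeds give identical splits.
#' @param positive_class label treated as positive (default: the
#'   alphabetically second class, matching the 0/1 coding of
#'   [fit_oplsda()]).
#' @return A list of class `mccv_result`: `mean` (a `performance`),
#'   `iterations` (per-iteration data frame), `n_iterations`,
#'   `train_fraction`, `seed`.
#' @export
monte_carlo_cv <- function(x, y, model_spec, n_iterations = 100L,
                           train_fraction = 0.9, seed = 1L,
                           positive_class = NULL) {
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("`x` rows must match `y`", call. = FALSE)
  if (is.null(positive_class)) positive_class <- sort(unique(y))[2L]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  rows <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    tr <- stratified_train_indices(y, train_fraction)
    te <- setdiff(seq_along(y), tr)
    model <- model_spec$fit(x[tr, , drop = FALSE], y[tr])
    pred <- model_spec$predict(model, x[te, , drop = FALSE])
    perf <- evaluate_performance(y[te], pred, positive_class)
    rows[[it]] <- data.frame(iteration = it, accuracy = perf$accuracy,
                             sensitivity = perf$sensitivity,
                             specificity = perf$specificity,
                             tp = perf$tp, tn = perf$tn,
                             fp = perf$fp, fn = perf$fn)
  }
  iters <- do.call(rbind, rows)
  mean_perf <- structure(list(accuracy = mean(iters$accuracy),
                              sensitivity = mean(iters$sensitivity),
                              specificity = mean(iters$specificity),
                              tp = sum(iters$tp), tn = sum(iters$tn),
                              fp = sum(iters$fp), fn = sum(iters$fn)),
                         class = "performance")
  structure(list(mean = mean_perf, iterations = iters,
                 n_iterations = n_iterations,
                 train_fraction = train_fraction, seed = seed,
                 positive_class = positive_class),
            class = "mccv_result")
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf("<mccv_result> %d iterations (train %.0f%%): mean ",
              x$n_iterations, 100 * x$train_fraction))
  print(x$mean)
  invisible(x)
}

#' Permutation p-value from counts
#'
#' The empirical p-value: the number of permutations with a strictly better
#' statistic than the observed one, divided by the number of permutations.
#'
#' @param n_better permutations strictly exceeding the observed statistic.
#' @param n_permutations total permutations.
#' @return The p-value in [0, 1].
#' @export
permutation_pvalue <- function(n_better, n_permutations) {
  if (n_permutations < 1L) stop("`n_permutations` must be >= 1", call. = FALSE)
  if (n_better < 0 || n_better > n_permutations)
    stop("`n_better` must be between 0 and `n_permutations`", call. = FALSE)
  n_better / n_permutations
}

#' Label-permutation test for a classification model
#'
#' Refits the model under randomly reassigned class labels and compares the
#' permuted mean MC-CV accuracies with the observed one.  The p-value is
#' the fraction of permutations with strictly greater accuracy.
#'
#' @param x,y,model_spec as in [monte_carlo_cv()].
#' @param n_permutations number of label permutations (default 1000).
#' @param n_cv_iterations MC-CV iterations inside each evaluation; the
#'   default 20 trades fidelity for tractability, 100 reproduces the full
#'   validation setting.
#' @param train_fraction,seed,positive_class as in [monte_carlo_cv()].
#' @return A list of class `permutation_result`: `observed`, `permuted`
#'   (vector of permuted statistics), `p_value`, `n_permutations`.
#' @export
permutation_test <- function(x, y, model_spec, n_permutations = 1000L,
                             n_cv_iterations = 20L, train_fraction = 0.9,
                             seed = 1L, positive_class = NULL) {
  y <- as.character(y)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  observed <- monte_carlo_cv(x, y, model_spec,
                             n_iterations = n_cv_iterations,
                             train_fraction = train_fraction,
                             seed = sample.int(.Machine$integer.max, 1L),
                             positive_class = positive_class)$mean$accuracy
  permuted <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    yp <- sample(y)
    permuted[b] <- monte_carlo_cv(x, yp, model_spec,
                                  n_iterations = n_cv_iterations,
                                  train_fraction = train_fraction,
                                  seed = sample.int(.Machine$integer.max, 1L),
                                  positive_class = positive_class)$mean$accuracy
  }
  structure(list(observed = observed, permuted = permuted,
                 p_value = permutation_pvalue(sum(permuted > observed),
                                              n_permutations),
                 n_permutations = n_permutations, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed accuracy %.1f%%, p = %s (%d permutations)\n",
              x$observed, format_pvalue(x$p_value, x$n_permutations),
              x$n_permutations))
  invisible(x)
}

#' Format a permutation p-value for reporting
#'
#' P-values below the resolution of the permutation test (1 /
#' `n_permutations`) are rendered as a bound, e.g. `"<0.001"` for 1000
#' permutations.
#'
#' @param p the p-value.
#' @param n_permutations permutations used to obtain it.
#' @param digits significant digits for values above the resolution.
#' @return A character scalar.
#' @export
format_pvalue <- function(p, n_permutations = 1000L, digits = 3L) {
  limit <- 1 / n_permutations
  if (p < limit) paste0("<", format(limit, scientific = FALSE))
  else format(round(p, digits), scientific = FALSE)
}
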