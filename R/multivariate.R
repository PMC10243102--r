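# Internal: scale a plain numeric matrix, returning the same structure as
# scale_profiles() so models can be fitted inside cross-validation folds
# without rebuilding a profile_matrix.
scale_values <- function(x, method = c("unit_variance", "center", "pareto")) {
  method <- match.arg(method)
  if (nrow(x) < 2L) stop("need at least 2 samples to scale", call. = FALSE)
  ctr <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  if (method != "center" && any(sds == 0))
    stop("zero-variance metabolite(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  scl <- switch(method,
                center = rep(1, ncol(x)),
                unit_variance = sds,
                pareto = sqrt(sds))
  names(scl) <- colnames(x)
  structure(list(values = sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/"),
                 center = ctr, scale = scl, method = method, groups = NULL),
            class = "scaled_matrix")
}

# Fix the sign of each loading vector so its largest-magnitude entry is
# positive; makes SVD-based fits deterministic.
fix_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal component analysis
#'
#' PCA of a centered/scaled matrix via singular-value decomposition, with a
#' fixed sign convention (the largest-magnitude loading of each component is
#' positive) so the output is deterministic.
#'
#' @param x a `scaled_matrix` (see [scale_profiles()]) or a numeric matrix
#'   already column-centered.
#' @param k number of components, at most `min(n - 1, m)`.
#' @return An object of class `pca_model` with `scores` (n x k), `loadings`
#'   (m x k, orthonormal columns), `explained` (fraction of total variance
#'   per component) and `k`.
#' @export
fit_pca <- function(x, k = 2L) {
  vals <- if (inherits(x, "scaled_matrix")) x$values else x
  n <- nrow(vals); m <- ncol(vals)
  if (k < 1L || k > min(n - 1L, m))
    stop("`k` must be between 1 and min(n - 1, m) = ", min(n - 1L, m),
         call. = FALSE)
  sv <- svd(vals, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  fixed <- fix_signs(sv$v, scores)
  total_var <- sum(vals^2)
  structure(list(scores = fixed$scores, loadings = fixed$loadings,
                 explained = sv$d[seq_len(k)]^2 / total_var, k = k),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components; explained variance: %s\n", x$k,
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

# map a two-class label vector onto 0/1 following the stored class order
encode_classes <- function(y, classes = NULL) {
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  if (length(classes) != 2L)
    stop("exactly two classes required, got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(y), classes)
  if (length(unknown))
    stop("unknown class label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  list(code = ifelse(y == classes[2L], 1, 0), classes = classes)
}

#' Two-class OPLS-DA
#'
#' Orthogonal projections to latent structures discriminant analysis in the
#' NIPALS style: `k_ortho` response-orthogonal components are extracted and
#' removed from the data, then a single predictive component is fitted.
#' With `k_ortho = 0` the model is exactly a 1-component PLS regression on
#' the 0/1 class code.
#'
#' Classes are coded alphabetically (first class 0, second class 1) unless
#' `classes` fixes the order; the decision threshold on the predicted
#' response is 0.5, with ties assigned to the first (code-0) class.
#'
#' @param x a `scaled_matrix` of training data.
#' @param y two-class label vector, one label per row of `x`.
#' @param k_ortho number of orthogonal components (>= 0).
#' @param classes optional length-2 character vector fixing the class order
#'   (second entry is coded 1).
#' @param threshold decision threshold on the predicted response.
#' @return An object of class `opls_model`.
#' @export
fit_oplsda <- function(x, y, k_ortho = 0L, classes = NULL, threshold = 0.5) {
  stopifnot(inherits(x, "scaled_matrix"))
  enc <- encode_classes(y, classes)
  if (length(enc$code) != nrow(x$values))
    stop("`y` must have one label per sample", call. = FALSE)
  if (length(unique(enc$code)) != 2L)
    stop("both classes must be present in `y`", call. = FALSE)
  if (k_ortho < 0) stop("`k_ortho` must be >= 0", call. = FALSE)

  X <- x$values
  yc <- enc$code - mean(enc$code)
  m <- ncol(X)
  W_o <- matrix(0, m, 0); P_o <- matrix(0, m, 0)
  T_o <- matrix(0, nrow(X), 0)
  for (j in seq_len(k_ortho)) {
    w <- drop(crossprod(X, yc)); w <- w / sqrt(sum(w^2))
    tt <- drop(X %*% w)
    p <- drop(crossprod(X, tt)) / sum(tt^2)
    w_o <- p - sum(w * p) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-10)
      stop("`k_ortho` too large: no orthogonal variation left at component ",
           j, call. = FALSE)
    w_o <- w_o / nw
    t_o <- drop(X %*% w_o)
    p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }
  w <- drop(crossprod(X, yc)); w <- w / sqrt(sum(w^2))
  tt <- drop(X %*% w)
  p <- drop(crossprod(X, tt)) / sum(tt^2)
  c_y <- sum(yc * tt) / sum(tt^2)

  structure(list(center = x$center, scale = x$scale,
                 scaling_method = x$method,
                 weights = w, scores = tt, loadings = p,
                 ortho_weights = W_o, ortho_scores = T_o, ortho_loadings = P_o,
                 y_loading = c_y, y_mean = mean(enc$code),
                 classes = enc$classes, threshold = threshold,
                 k_ortho = k_ortho, n_components_total = 1L + k_ortho,
                 metabolites = colnames(x$values)),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> %s (0) vs %s (1); 1 predictive + %d orthogonal component(s)\n",
              x$classes[1], x$classes[2], x$k_ortho))
  invisible(x)
}

# project raw (unscaled) new data through the stored scaling and orthogonal
# filters, returning the filtered scaled matrix
opls_filter <- function(model, newdata) {
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), model$metabolites))
    stop("metabolite columns do not match the training data", call. = FALSE)
  X <- sweep(sweep(newdata, 2L, model$center, "-"), 2L, model$scale, "/")
  for (j in seq_len(ncol(model$ortho_weights))) {
    t_o <- drop(X %*% model$ortho_weights[, j])
    X <- X - tcrossprod(t_o, model$ortho_loadings[, j])
  }
  X
}

#' Predict from an OPLS-DA model
#'
#' @param object an `opls_model`.
#' @param newdata numeric matrix of raw (unscaled) values with the training
#'   metabolite columns, or a `profile_matrix`.
#' @param type `"class"` for labels, `"response"` for the continuous
#'   predicted response on the 0/1 scale, `"both"` for a data frame.
#' @param ... unused.
#' @return Labels, responses, or a data frame with both.  A response equal
#'   to the threshold is assigned to the first (code-0) class.
#' @export
predict.opls_model <- function(object, newdata,
                               type = c("class", "response", "both"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "profile_matrix")) newdata <- newdata$values
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  X <- opls_filter(object, newdata)
  resp <- drop(X %*% object$weights) * object$y_loading + object$y_mean
  label <- ifelse(unname(resp) > object$threshold,
                  object$classes[2L], object$classes[1L])
  switch(type,
         class = label,
         response = resp,
         both = data.frame(response = resp, class = label,
                           stringsAsFactors = FALSE))
}

#' Multi-class PLS-DA
#'
#' Standard NIPALS PLS2 regression against a one-hot class-indicator matrix,
#' used for the indicative discrimination of three or more groups.  New
#' samples are assigned to the class with the largest predicted indicator.
#'
#' @param x a `scaled_matrix` of training data.
#' @param y class label vector (>= 2 classes).
#' @param k number of components.
#' @return An object of class `plsda_model` with mutually orthogonal score
#'   columns.
#' @export
fit_plsda <- function(x, y, k = 2L) {
  stopifnot(inherits(x, "scaled_matrix"))
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  Y <- outer(y, classes, "==") + 0
  colnames(Y) <- classes
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_means, "-")
  X <- x$values
  n <- nrow(X); m <- ncol(X)
  if (k < 1L || k > min(n - 1L, m)) stop("invalid `k`", call. = FALSE)

  W <- matrix(0, m, k); P <- matrix(0, m, k); Q <- matrix(0, length(classes), k)
  Tm <- matrix(0, n, k)
  for (a in seq_len(k)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    for (iter in 1:500) {
      w <- drop(crossprod(X, u)); w <- w / sqrt(sum(w^2))
      tt <- drop(X %*% w)
      q <- drop(crossprod(Yc, tt)) / sum(tt^2)
      u_new <- drop(Yc %*% q) / sum(q^2)
      if (sum((u_new - u)^2) < 1e-12 * sum(u_new^2)) { u <- u_new; break }
      u <- u_new
    }
    p <- drop(crossprod(X, tt)) / sum(tt^2)
    X <- X - tcrossprod(tt, p)
    Yc <- Yc - tcrossprod(tt, q)
    W[, a] <- w; P[, a] <- p; Q[, a] <- q; Tm[, a] <- tt
  }
  structure(list(center = x$center, scale = x$scale,
                 scaling_method = x$method,
                 weights = W, loadings = P, y_loadings = Q, scores = Tm,
                 y_means = y_means, classes = classes, k = k,
                 metabolites = colnames(x$values)),
            class = "plsda_model")
}

#' Predict from a PLS-DA model
#'
#' @param object a `plsda_model`.
#' @param newdata raw numeric matrix or `profile_matrix` with the training
#'   metabolite columns.
#' @param type `"class"` or `"response"` (predicted indicator matrix).
#' @param ... unused.
#' @export
predict.plsda_model <- function(object, newdata,
                                type = c("class", "response"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "profile_matrix")) newdata <- newdata$values
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$metabolites))
    stop("metabolite columns do not match the training data", call. = FALSE)
  X <- sweep(sweep(newdata, 2L, object$center, "-"), 2L, object$scale, "/")
  # B = W (P'W)^-1 Q'
  B <- object$weights %*%
    solve(crossprod(object$loadings, object$weights), t(object$y_loadings))
  Yhat <- sweep(X %*% B, 2L, object$y_means, "+")
  colnames(Yhat) <- object$classes
  if (type == "response") return(Yhat)
  object$classes[max.col(Yhat, ties.method = "first")]
}

#' Smallest component count achieving maximal accuracy
#'
#' The component-selection rule: among candidate component counts, keep the
#' smallest whose (cross-validated) accuracy equals the maximum over all
#' candidates.
#'
#' @param accuracies numeric vector, accuracy per component count 1..length.
#' @return The chosen component count (integer).
#' @export
pick_min_argmax <- function(accuracies) {
  if (!length(accuracies)) stop("empty accuracy profile", call. = FALSE)
  which.max(accuracies)  # which.max returns the first (smallest) maximizer
}

#' Select the total number of OPLS-DA components
#'
#' Runs Monte-Carlo cross-validation for each candidate total component
#' count (1 predictive + 0..max_total-1 orthogonal) and returns the smallest
#' count achieving the maximal mean CV accuracy.
#'
#' @param x raw numeric matrix (samples x metabolites).
#' @param y two-class labels.
#' @param max_total maximum total components to consider (>= 1).
#' @param n_iterations,train_fraction,seed passed to [monte_carlo_cv()].
#' @param scaling scaling method used inside each fit.
#' @param classes optional class order (second = positive).
#' @return List with `n_components_total`, `k_ortho`, and the `accuracy`
#'   profile over candidate counts.
#' @export
select_components <- function(x, y, max_total = 5L, n_iterations = 20L,
                              train_fraction = 0.9, seed = 1L,
                              scaling = "unit_variance", classes = NULL) {
  if (max_total < 1L) stop("`max_total` must be >= 1", call. = FALSE)
  acc <- vapply(seq_len(max_total), function(k_tot) {
    spec <- opls_spec(k_ortho = k_tot - 1L, scaling = scaling,
                      classes = classes)
    res <- monte_carlo_cv(x, y, spec, n_iterations = n_iterations,
                          train_fraction = train_fraction, seed = seed)
    res$mean$accuracy
  }, numeric(1))
  k <- pick_min_argmax(acc)
  list(n_components_total = k, k_ortho = k - 1L, accuracy = acc)
}
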