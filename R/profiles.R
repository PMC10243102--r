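#' Construct a metabolite profile matrix
#'
#' The central data container: a samples x metabolites table of nonnegative
#' concentrations together with per-sample group labels.  Rows are samples,
#' columns metabolites.  After total-area normalization each row holds
#' dimensionless fractions summing to 1.
#'
#' @param values numeric matrix, samples x metabolites, nonnegative, no
#'   missing cells.  Row names are sample ids, column names metabolite names.
#' @param groups character or factor of per-sample group labels, length
#'   `nrow(values)`.
#' @param normalized logical flag; `TRUE` once rows have been divided by
#'   their total area.
#' @return An object of class `profile_matrix`.
#' @export
profile_matrix <- function(values, groups, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample ids as row names and metabolite names as column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated metabolite names", call. = FALSE)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    stop("missing values at ",
         paste(sprintf("[%s, %s]", rownames(values)[bad[, 1]],
                       colnames(values)[bad[, 2]]), collapse = "; "),
         call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)
    stop("negative concentrations at ",
         paste(sprintf("[%s, %s]", rownames(values)[bad[, 1]],
                       colnames(values)[bad[, 2]]), collapse = "; "),
         call. = FALSE)
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(values))
    stop("`groups` must have one label per sample", call. = FALSE)
  structure(list(values = values, groups = groups,
                 normalized = isTRUE(normalized)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d samples x %d metabolites (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "total-area normalized" else "raw"))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$values)

sample_ids <- function(m) rownames(m$values)
metabolite_names <- function(m) colnames(m$values)

#' Read a profile matrix from delimited text
#'
#' Expects a header row and columns `sample_id`, `group`, then one column
#' per metabolite.  Missing or negative cells and duplicated sample ids are
#' rejected with an error naming the offenders.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return A [profile_matrix()].
#' @export
read_profiles <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  need <- c("sample_id", "group")
  if (!all(need %in% names(df)))
    stop("header must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  met <- setdiff(names(df), need)
  if (length(met) == 0L) stop("no metabolite columns found", call. = FALSE)
  vals <- as.matrix(df[, met, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df$sample_id)
  profile_matrix(vals, df$group)
}

#' Write a profile matrix as CSV
#'
#' Inverse of [read_profiles()]: columns `sample_id`, `group`, then the
#' metabolites, comma-separated with a header row.
#'
#' @param m a `profile_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(m, path) {
  stopifnot(inherits(m, "profile_matrix"))
  df <- data.frame(sample_id = sample_ids(m), group = m$groups,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(m$values, check.names = FALSE))
  # metabolite names may contain commas (e.g. N,N-dimethylglycine): quote
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Remove metabolites from a profile
#'
#' Applied before normalization: contaminant or artifact signals (e.g.
#' glycerol leaching from ultrafiltration membranes, environmental propylene
#' glycol) are dropped so they cannot distort the total-area denominator.
#'
#' @param m a `profile_matrix`.
#' @param names metabolite names to remove; must all be present.
#' @return A `profile_matrix` with the remaining columns in original order.
#' @export
exclude_metabolites <- function(m, names) {
  stopifnot(inherits(m, "profile_matrix"))
  if (length(names) == 0L) return(m)
  missing <- setdiff(names, metabolite_names(m))
  if (length(missing))
    stop("unknown metabolite(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- setdiff(metabolite_names(m), names)
  profile_matrix(m$values[, keep, drop = FALSE], m$groups,
                 normalized = m$normalized)
}

#' Total-area normalization
#'
#' Divides each sample's concentrations by their sum, removing global
#' dilution differences between plasma samples.  Idempotent and invariant
#' to per-sample rescaling.
#'
#' @param m a `profile_matrix` whose rows all have positive sums.
#' @return A normalized `profile_matrix` (rows sum to 1).
#' @export
normalize_total_area <- function(m) {
  stopifnot(inherits(m, "profile_matrix"))
  rs <- rowSums(m$values)
  if (any(rs <= 0))
    stop("nonpositive row total for sample(s): ",
         paste(sample_ids(m)[rs <= 0], collapse = ", "), call. = FALSE)
  profile_matrix(m$values / rs, m$groups, normalized = TRUE)
}

#' Center and scale a profile matrix
#'
#' Produces the column-wise centered (and optionally scaled) matrix used by
#' the multivariate models, keeping the per-metabolite center and scale
#' parameters so new samples can be projected onto a fitted model.
#' `unit_variance` (autoscaling) is the default throughout the package;
#' `pareto` divides by the square root of the standard deviation.  Standard
#' deviations use the n-1 denominator.
#'
#' @param m a `profile_matrix` with at least 2 samples.
#' @param method one of `"center"`, `"unit_variance"`, `"pareto"`.
#' @return An object of class `scaled_matrix` with elements `values`,
#'   `center`, `scale`, `method`, `groups`.
#' @export
scale_profiles <- function(m, method = c("unit_variance", "center", "pareto")) {
  stopifnot(inherits(m, "profile_matrix"))
  method <- match.arg(method)
  if (nrow(m$values) < 2L) stop("need at least 2 samples to scale", call. = FALSE)
  ctr <- colMeans(m$values)
  sds <- apply(m$values, 2L, stats::sd)
  if (method != "center" && any(sds == 0))
    stop("zero-variance metabolite(s): ",
         paste(metabolite_names(m)[sds == 0], collapse = ", "), call. = FALSE)
  scl <- switch(method,
                center = rep(1, ncol(m$values)),
                unit_variance = sds,
                pareto = sqrt(sds))
  names(scl) <- metabolite_names(m)
  vals <- sweep(sweep(m$values, 2L, ctr, "-"), 2L, scl, "/")
  structure(list(values = vals, center = ctr, scale = scl,
                 method = method, groups = m$groups),
            class = "scaled_matrix")
}

#' Apply stored scaling parameters to new data
#'
#' @param s a `scaled_matrix` (source of center/scale parameters).
#' @param values numeric matrix with the same metabolite columns as the
#'   training data (names and order are checked).
#' @return The centered/scaled matrix.
#' @export
apply_scaling <- function(s, values) {
  stopifnot(inherits(s, "scaled_matrix"))
  if (is.null(colnames(values)) ||
      !identical(colnames(values), names(s$center)))
    stop("metabolite columns do not match the training data", call. = FALSE)
  sweep(sweep(values, 2L, s$center, "-"), 2L, s$scale, "/")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("<scaled_matrix> %d x %d, method = %s\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

#' Subset a profile matrix by group and/or metabolite
#'
#' @param m a `profile_matrix`.
#' @param groups group labels to keep (default all).
#' @param metabolites metabolite names to keep (default all).
#' @return A `profile_matrix`.
#' @export
subset_profiles <- function(m, groups = NULL, metabolites = NULL) {
  stopifnot(inherits(m, "profile_matrix"))
  rows <- if (is.null(groups)) rep(TRUE, nrow(m$values)) else m$groups %in% groups
  if (!is.null(groups)) {
    unknown <- setdiff(groups, unique(m$groups))
    if (length(unknown))
      stop("unknown group(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cols <- metabolite_names(m)
  if (!is.null(metabolites)) {
    missing <- setdiff(metabolites, cols)
    if (length(missing))
      stop("unknown metabolite(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    cols <- metabolites
  }
  profile_matrix(m$values[rows, cols, drop = FALSE], m$groups[rows],
                 normalized = m$normalized)
}
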