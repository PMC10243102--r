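#' Serialize an OPLS-DA model to JSON
#'
#' Writes every parameter needed to reproduce predictions (scaling, weights,
#' loadings, y-loading, class coding, threshold) to a documented JSON
#' layout, so long ensemble runs are resumable and models auditable.
#'
#' @param model an `opls_model`.
#' @param path output file; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
opls_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "opls_model"))
  payload <- list(
    format = "oplsrisk/opls_model/1",
    metabolites = model$metabolites,
    scaling = list(method = model$scaling_method,
                   center = unname(model$center),
                   scale = unname(model$scale)),
    predictive = list(weights = unname(model$weights),
                      loadings = unname(model$loadings),
                      y_loading = model$y_loading,
                      y_mean = model$y_mean),
    orthogonal = list(k = model$k_ortho,
                      weights = unname(model$ortho_weights),
                      loadings = unname(model$ortho_loadings)),
    classes = model$classes,
    threshold = model$threshold)
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Restore an OPLS-DA model from JSON
#'
#' @param path file path or JSON string produced by [opls_to_json()].
#' @return An `opls_model` whose predictions match the serialized model.
#' @export
opls_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (!identical(x$format, "oplsrisk/opls_model/1"))
    stop("not a serialized OPLS-DA model", call. = FALSE)
  m <- length(x$metabolites)
  as_mat <- function(v) {
    if (is.null(v) || !length(v)) return(matrix(0, m, 0))
    matrix(as.numeric(unlist(v)), nrow = m)
  }
  structure(list(center = stats::setNames(x$scaling$center, x$metabolites),
                 scale = stats::setNames(x$scaling$scale, x$metabolites),
                 scaling_method = x$scaling$method,
                 weights = x$predictive$weights,
                 scores = NULL,
                 loadings = x$predictive$loadings,
                 ortho_weights = as_mat(x$orthogonal$weights),
                 ortho_scores = NULL,
                 ortho_loadings = as_mat(x$orthogonal$loadings),
                 y_loading = x$predictive$y_loading,
                 y_mean = x$predictive$y_mean,
                 classes = x$classes, threshold = x$threshold,
                 k_ortho = x$orthogonal$k,
                 n_components_total = 1L + x$orthogonal$k,
                 metabolites = x$metabolites),
            class = "opls_model")
}
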