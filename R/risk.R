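#' Ensemble specification for external risk classification
#'
#' Settings for one discrimination ensemble: a case group (a PC stage) is
#' discriminated from a control group (DM2, or early-stage PC for the
#' early/late assignment), `n_models` OPLS-DA models are built on
#' independent random train/validation splits, and only models whose
#' held-out accuracy exceeds `min_accuracy` are used to classify external
#' samples.  Each qualifying model scores an independent random subsample of
#' `external_subsample_size` external samples, balancing group sizes.
#'
#' @param control,case the two group labels; `case` is the PC side whose
#'   classifications are counted as votes.
#' @param n_models number of models (default 20).
#' @param min_accuracy qualification threshold in percent (strict, default 80).
#' @param external_subsample_size external samples scored per model
#'   (default 25).
#' @param k_ortho orthogonal components of each OPLS-DA model.
#' @param train_fraction per-model training fraction.
#' @param seed integer seed.
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(control, case, n_models = 20L, min_accuracy = 80,
                          external_subsample_size = 25L, k_ortho = 1L,
                          train_fraction = 0.9, seed = 1L) {
  if (n_models < 1L) stop("`n_models` must be >= 1", call. = FALSE)
  if (external_subsample_size < 1L)
    stop("`external_subsample_size` must be >= 1", call. = FALSE)
  structure(list(control = control, case = case, n_models = n_models,
                 min_accuracy = min_accuracy,
                 external_subsample_size = external_subsample_size,
                 k_ortho = k_ortho, train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Build a discrimination ensemble
#'
#' Fits `n_models` OPLS-DA models between the two groups named in `spec`.
#' Every
#' model uses all samples of both groups, but draws its own stratified
#' random train/validation split: it is fitted on the training part and its
#' accuracy measured on the held-out part (one Monte-Carlo CV cycle per
#' model).  Models with held-out accuracy strictly above `min_accuracy`
#' qualify for external classification.
#'
#' @param m a `profile_matrix` containing both groups named in `spec`.
#' @param spec an [ensemble_spec()].
#' @return A list of class `opls_ensemble`: `models`, `accuracies`
#'   (percent), `qualifying` (indices), `spec`.  An empty qualifying set is
#'   legal and must be handled downstream.
#' @export
build_ensemble <- function(m, spec) {
  stopifnot(inherits(m, "profile_matrix"), inherits(spec, "ensemble_spec"))
  sub <- subset_profiles(m, groups = c(spec$control, spec$case))
  x <- sub$values; y <- sub$groups
  if (sum(y == spec$control) < 5L || sum(y == spec$case) < 5L)
    stop("both groups need >= 5 samples", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  models <- vector("list", spec$n_models)
  acc <- numeric(spec$n_models)
  for (i in seq_len(spec$n_models)) {
    tr <- stratified_train_indices(y, spec$train_fraction)
    te <- setdiff(seq_along(y), tr)
    fit <- fit_oplsda(scale_values(x[tr, , drop = FALSE]), y[tr],
                      k_ortho = spec$k_ortho,
                      classes = c(spec$control, spec$case))
    pred <- predict(fit, x[te, , drop = FALSE])
    acc[i] <- evaluate_performance(y[te], pred, spec$case)$accuracy
    models[[i]] <- fit
  }
  structure(list(models = models, accuracies = acc,
                 qualifying = which(acc > spec$min_accuracy), spec = spec),
            class = "opls_ensemble")
}

#' @export
print.opls_ensemble <- function(x, ...) {
  cat(sprintf("<opls_ensemble> %s vs %s: %d models, %d qualifying (accuracy > %g%%), mean accuracy %.1f%%\n",
              x$spec$control, x$spec$case, length(x$models),
              length(x$qualifying), x$spec$min_accuracy, mean(x$accuracies)))
  invisible(x)
}

#' Vote records from raw counts
#'
#' Builds the per-sample classification record from vote and application
#' counts: the ratio is `100 * votes / applications` percent, undefined
#' (`NA`) for samples never included in a qualifying model's subsample.
#'
#' @param sample sample identifiers.
#' @param votes number of qualifying models classifying the sample as the
#'   case (PC) group.
#' @param applications number of qualifying models whose external subsample
#'   contained the sample.
#' @return A data frame of class `vote_records` with columns `sample`,
#'   `votes`, `applications`, `ratio`.
#' @export
vote_records <- function(sample, votes, applications) {
  if (any(votes < 0) || any(applications < 0) || any(votes > applications))
    stop("votes must satisfy 0 <= votes <= applications", call. = FALSE)
  out <- data.frame(sample = as.character(sample), votes = votes,
                    applications = applications,
                    ratio = ifelse(applications > 0,
                                   100 * votes / applications, NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("vote_records", "data.frame")
  out
}

#' Classify an external cohort with a qualifying ensemble
#'
#' Each qualifying model draws an independent seeded random subsample of
#' the external cohort (balancing group sizes) and classifies it; a
#' classification into the case (PC) group counts as one vote.  Per-sample
#' votes and applications are accumulated into [vote_records()].
#'
#' @param ensemble an `opls_ensemble` with at least one qualifying model.
#' @param external a `profile_matrix` of external samples (e.g. the RODM
#'   cohort), same metabolite columns as the training data.
#' @param seed integer seed for the subsample draws.
#' @return A `vote_records` data frame covering every external sample.
#' @export
classify_external <- function(ensemble, external, seed = 1L) {
  stopifnot(inherits(ensemble, "opls_ensemble"),
            inherits(external, "profile_matrix"))
  if (!length(ensemble$qualifying))
    stop("no qualifying models in the ensemble", call. = FALSE)
  ids <- rownames(external$values)
  n_ext <- length(ids)
  size <- min(ensemble$spec$external_subsample_size, n_ext)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  votes <- stats::setNames(integer(n_ext), ids)
  apps <- stats::setNames(integer(n_ext), ids)
  for (i in ensemble$qualifying) {
    pick <- sample(n_ext, size)
    pred <- predict(ensemble$models[[i]],
                    external$values[pick, , drop = FALSE])
    apps[pick] <- apps[pick] + 1L
    votes[pick] <- votes[pick] + (pred == ensemble$spec$case)
  }
  vote_records(ids, unname(votes), unname(apps))
}

#' Select at-risk samples from vote records
#'
#' The selection rule: a sample is flagged by an ensemble if it was
#' classified as PC at least once, i.e. its classification ratio is
#' strictly positive.  (This is the only threshold consistent with the
#' published per-ensemble selection counts; see the README.)
#'
#' @param records a `vote_records` data frame.
#' @return Character vector of selected sample ids.
#' @export
select_at_risk <- function(records) {
  stopifnot(inherits(records, "data.frame"))
  records$sample[!is.na(records$ratio) & records$ratio > 0]
}

#' Majority early/late labels from a stage ensemble
#'
#' Converts the early-vs-late (PC I+II vs PC IV) ensemble's vote records
#' into per-sample stage labels: `"late"` when at least half of the models
#' that saw the sample classified it as the late stage (ties go to late,
#' the conservative direction for surveillance), `"early"` otherwise; `NA`
#' for samples with no applications.
#'
#' @param records `vote_records` whose votes count late-stage
#'   classifications.
#' @return Named character vector of `"early"`/`"late"`/`NA` per sample.
#' @export
stage_majority_labels <- function(records) {
  lab <- ifelse(is.na(records$ratio), NA_character_,
                ifelse(records$ratio >= 50, "late", "early"))
  stats::setNames(lab, records$sample)
}

#' Early/late stage assignment and cross-model agreement
#'
#' Labels every at-risk sample from two independent sources and measures
#' their concordance.  Source A derives from the stage-vs-DM2 ensembles: a
#' sample selected by the early-stage (PC I+II vs DM2) ensemble is labeled
#' early, all other at-risk samples late.  Source B is the majority label
#' of the dedicated early-vs-late (PC I+II vs PC IV) ensemble.  Agreement
#' is the percentage of at-risk samples on which the sources concur (over
#' samples where both are defined).
#'
#' @param at_risk character vector of at-risk sample ids (nonempty).
#' @param early_selected samples selected by the early-stage-vs-DM2
#'   ensemble.
#' @param stage_labels named `"early"`/`"late"` vector, e.g. from
#'   [stage_majority_labels()].
#' @return A list of class `stage_assignment`: `labels` (data frame with
#'   `sample`, `source_a`, `source_b`, `concordant`), `agreement` (percent),
#'   `n_early`, `n_late` (source B counts).
#' @export
assign_stage <- function(at_risk, early_selected, stage_labels) {
  if (!length(at_risk)) stop("empty at-risk set", call. = FALSE)
  source_a <- ifelse(at_risk %in% early_selected, "early", "late")
  source_b <- unname(stage_labels[at_risk])
  ok <- !is.na(source_b)
  conc <- source_a == source_b
  structure(list(labels = data.frame(sample = at_risk, source_a = source_a,
                                     source_b = source_b,
                                     concordant = conc,
                                     stringsAsFactors = FALSE),
                 agreement = 100 * sum(conc[ok]) / sum(ok),
                 n_early = sum(source_b == "early", na.rm = TRUE),
                 n_late = sum(source_b == "late", na.rm = TRUE)),
            class = "stage_assignment")
}

#' Full external risk-classification report
#'
#' Runs the complete prediction scheme: one ensemble per PC stage against
#' the control group classifies the external cohort by vote ratio; the
#' union of per-ensemble selections is the at-risk set; a fourth ensemble
#' (early vs late stage) assigns early/late labels, compared against the
#' stage-vs-control pattern.
#'
#' @param m a `profile_matrix` containing the control, stage and external
#'   groups.
#' @param control control group label (default `"DM2"`).
#' @param stages ordered PC stage group labels (first = early, last =
#'   late).
#' @param external external cohort group label (default `"RODM"`).
#' @param n_models,min_accuracy,external_subsample_size,k_ortho,train_fraction
#'   passed to every [ensemble_spec()].
#' @param seed integer seed; per-ensemble seeds are derived from it.
#' @return A list of class `risk_report`: `records` (named list of
#'   `vote_records` per stage ensemble), `stage_records`, `selected`
#'   (named list per ensemble), `at_risk`, `stage_assignment` (or `NULL`
#'   when nothing was selected), `ensembles`, `n_models_total`.
#' @export
predict_risk <- function(m, control = "DM2",
                         stages = c("PC_I_II", "PC_III", "PC_IV"),
                         external = "RODM", n_models = 20L,
                         min_accuracy = 80, external_subsample_size = 25L,
                         k_ortho = 1L, train_fraction = 0.9, seed = 1L) {
  stopifnot(inherits(m, "profile_matrix"))
  ext <- subset_profiles(m, groups = external)
  ensembles <- list(); records <- list(); selected <- list()
  for (i in seq_along(stages)) {
    spec <- ensemble_spec(control, stages[i], n_models = n_models,
                          min_accuracy = min_accuracy,
                          external_subsample_size = external_subsample_size,
                          k_ortho = k_ortho, train_fraction = train_fraction,
                          seed = seed + i)
    ens <- build_ensemble(m, spec)
    ensembles[[stages[i]]] <- ens
    if (length(ens$qualifying)) {
      rec <- classify_external(ens, ext, seed = seed + 100L + i)
      records[[stages[i]]] <- rec
      selected[[stages[i]]] <- select_at_risk(rec)
    } else {
      records[[stages[i]]] <- vote_records(rownames(ext$values),
                                           integer(nrow(ext$values)),
                                           integer(nrow(ext$values)))
      selected[[stages[i]]] <- character(0)
    }
  }
  at_risk <- sort(unique(unlist(selected)))

  early <- stages[1L]; late <- stages[length(stages)]
  stage_spec <- ensemble_spec(early, late, n_models = n_models,
                              min_accuracy = min_accuracy,
                              external_subsample_size = external_subsample_size,
                              k_ortho = k_ortho,
                              train_fraction = train_fraction,
                              seed = seed + length(stages) + 1L)
  stage_ens <- build_ensemble(m, stage_spec)
  stage_records <- if (length(stage_ens$qualifying))
    classify_external(stage_ens, ext, seed = seed + 200L)
  else vote_records(rownames(ext$values), integer(nrow(ext$values)),
                    integer(nrow(ext$values)))

  assignment <- if (length(at_risk))
    assign_stage(at_risk, selected[[early]],
                 stage_majority_labels(stage_records))
  else NULL

  structure(list(records = records, stage_records = stage_records,
                 selected = selected, at_risk = at_risk,
                 stage_assignment = assignment,
                 ensembles = c(ensembles, list(stage = stage_ens)),
                 n_models_total = n_models * length(stages)),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("<risk_report> %d stage-vs-control models; at-risk samples: %s\n",
              x$n_models_total,
              if (length(x$at_risk)) paste(x$at_risk, collapse = ", ")
              else "none selected"))
  if (!is.null(x$stage_assignment))
    cat(sprintf("stage assignment: %d early, %d late; agreement %.1f%%\n",
                x$stage_assignment$n_early, x$stage_assignment$n_late,
                x$stage_assignment$agreement))
  invisible(x)
}

#' Format a classification ratio
#'
#' Renders a vote ratio the way the report tables print it, e.g.
#' `"38.5% (5/13)"`; samples with no applications render as `"-"`.
#'
#' @param votes,applications integer counts.
#' @return Character vector.
#' @export
format_ratio <- function(votes, applications) {
  ifelse(applications > 0,
         sprintf("%.1f%% (%d/%d)", 100 * votes / applications,
                 votes, applications),
         "-")
}
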