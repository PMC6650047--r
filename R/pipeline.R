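#' Run the full four-stage analysis on one dataset
#'
#' Executes, in order and with isolated random streams: (1) feature
#' engineering — symmetry augmentation for double-leg exercises, memory
#' matrix accumulation over resampled subject subsets, robust-phase
#' extraction and phase-mean featurization; (2) technique selection — the
#' full panel under raw and z-scored features across one set of
#' subject-level shuffle splits, plus the random-guess baseline; (3) forward
#' wrapper feature selection with the winning technique and the elbow-based
#' minimal feature model; (4) final k-fold re-validation of the minimal
#' model. Multi-level evaluation (limb/group/subject confusions,
#' sensitivities, meaningfulness) is computed for the minimal model.
#'
#' @param dataset a `movement_dataset`.
#' @param config an [analysis_config()].
#' @param techniques panel subset to benchmark (default: full panel).
#' @param run_kfold set `FALSE` to skip the final k-fold stage.
#' @return an object of class `pipeline_report`; see Details for fields.
#' @details Report fields: `phases`, `features` (feature matrix), `ranking`
#'   (technique table + winner), `guess` (per-split accuracies and best
#'   guess), `trace` (selection trace), `minimal` (labels), `minimal_result`
#'   (technique_result on the minimal model), `confusion` (limb-level
#'   matrix), `group` (binary collapse), `sensitivity`, `consistency`
#'   (true-member fractions), `meaningful`, `kfold`, and `config`.
#' @export
run_full_analysis <- function(dataset, config, techniques = technique_panel(),
                              run_kfold = TRUE) {
  stopifnot(inherits(dataset, "movement_dataset"),
            inherits(config, "analysis_config"))
  issues <- validate_structure(dataset)
  if (nrow(issues)) {
    stop("feature engineering: dataset fails structural validation (",
         nrow(issues), " issue(s)); see validate_structure()")
  }
  # stage 1: feature engineering
  augmented <- augment_symmetry(dataset)
  support <- build_support(augmented, config)
  phases <- robust_phases(support, config)
  if (!nrow(phases)) {
    stop("feature engineering: no robust phases detected")
  }
  features <- build_feature_matrix(augmented, phases, config)

  # stage 2: technique selection
  plans <- plan_splits(features, config)
  ranking <- rank_techniques(features, plans, config, techniques = techniques)
  guess <- guess_baseline(features, plans, config)

  # stage 3: feature selection
  trace <- forward_select(features, ranking$winner, plans, config)
  minimal <- minimal_model(trace)
  minimal_result <- evaluate_technique(subset_features(features, minimal),
                                       ranking$winner, plans, config)
  cm <- accumulate_confusion(minimal_result$records)
  group <- collapse_to_group(cm)
  sens <- class_sensitivity(cm)
  consistency <- subject_consistency(minimal_result$records)
  meaningful <- meaningfulness(minimal_result, guess$best_guess)

  # stage 4: final validation
  kfold <- if (run_kfold) {
    kfold_validate(subset_features(features, minimal), ranking$winner, config)
  } else NULL

  structure(list(
    exercise_id = dataset$exercise_id,
    phases = phases,
    features = features,
    ranking = ranking,
    guess = guess,
    trace = trace,
    minimal = minimal,
    minimal_result = minimal_result,
    confusion = cm,
    group = group,
    sensitivity = sens,
    consistency = consistency,
    meaningful = meaningful,
    kfold = kfold,
    config = config
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> exercise %s\n", x$exercise_id))
  cat(sprintf("  %d robust phases -> %d features over %d observations\n",
              nrow(x$phases), nrow(x$features$values), ncol(x$features$values)))
  cat(sprintf("  winning technique: %s (mean accuracy %.1f%%)\n",
              x$ranking$winner,
              100 * x$ranking$results[[x$ranking$winner]]$mean_accuracy))
  cat(sprintf("  best guess: %.1f%%\n", 100 * x$guess$best_guess))
  cat(sprintf("  minimal model (%d feature%s): %s\n", length(x$minimal),
              if (length(x$minimal) == 1) "" else "s",
              paste(x$minimal, collapse = "; ")))
  cat(sprintf("  minimal-model accuracy %.1f%%, meaningful: %s\n",
              100 * x$minimal_result$mean_accuracy, x$meaningful))
  if (!is.null(x$kfold)) {
    cat(sprintf("  k-fold re-validation: %.1f +/- %.1f%% (lowest %.1f%%)\n",
                100 * x$kfold$mean, 100 * x$kfold$sd, 100 * x$kfold$lowest))
  }
  invisible(x)
}

#' Write the headline numbers of a pipeline report as JSON
#'
#' Every value in the summary is recomputable from the report's stored
#' records; the JSON is a convenience view, not the primary artifact.
#'
#' @param report a `pipeline_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report_summary <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  obj <- list(
    schema = "limbclass-report-1",
    exercise_id = report$exercise_id,
    n_phases = nrow(report$phases),
    n_features = nrow(report$features$values),
    winner = report$ranking$winner,
    ranking = report$ranking$table,
    best_guess = report$guess$best_guess,
    selected = report$trace$selected,
    accuracy_curve = report$trace$f,
    elbow_n = report$trace$elbow_n,
    minimal = report$minimal,
    minimal_mean_accuracy = report$minimal_result$mean_accuracy,
    confusion = as.data.frame(as.table(report$confusion)),
    sensitivity = as.list(report$sensitivity),
    binary_accuracy = report$group$accuracy,
    true_fraction = as.list(report$consistency$true_fraction),
    meaningful = report$meaningful,
    kfold = if (!is.null(report$kfold)) {
      report$kfold[c("per_fold_accuracy", "mean", "sd", "lowest")]
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
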