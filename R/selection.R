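#' Forward wrapper feature selection with collinearity pruning
#'
#' Starting from an empty model base, each round evaluates every remaining
#' candidate feature joined to the current base across the full split plan
#' (via [evaluate_technique()] with the chosen technique), appends the
#' candidate with the highest mean accuracy (ties break by lowest feature
#' index), and removes from the candidate pool both the winner and every
#' remaining feature whose absolute Pearson correlation with it (computed
#' over all observations) exceeds `config$corr_threshold`. Selection stops
#' when `config$max_features` features are selected or the pool is empty.
#' The same split plans are reused for every candidate so that candidate
#' comparisons are paired.
#'
#' @param features a `feature_matrix`.
#' @param technique_id one of [technique_panel()].
#' @param plans split plans from [plan_splits()].
#' @param config an [analysis_config()].
#' @return an object of class `selection_trace`: `technique_id`, `selected`
#'   (ordered labels), `selected_idx`, `f` (accuracy curve, one entry per
#'   selected feature), `pruned` (named list: selected label -> pruned
#'   labels), `elbow_n`.
#' @export
forward_select <- function(features, technique_id, plans, config) {
  stopifnot(inherits(features, "feature_matrix"))
  i_total <- nrow(features$values)
  if (i_total < 1) stop("empty feature matrix")
  pool <- seq_len(i_total)
  base <- integer(0)
  f <- numeric(0)
  pruned <- list()
  labels <- features$features$label
  # collinearity computed once over all observations
  while (length(base) < config$max_features && length(pool) > 0) {
    cand_acc <- vapply(pool, function(j) {
      evaluate_technique(subset_features(features, c(base, j)), technique_id,
                        plans, config)$mean_accuracy
    }, numeric(1))
    best <- pool[which.max(cand_acc)]   # first max -> lowest feature index
    base <- c(base, best)
    f <- c(f, max(cand_acc))
    pool <- setdiff(pool, best)
    if (length(pool)) {
      r <- abs(suppressWarnings(stats::cor(features$values[best, ],
                                           t(features$values[pool, , drop = FALSE]))))
      r[is.na(r)] <- 0
      drop <- pool[r > config$corr_threshold]
      if (length(drop)) {
        pruned[[labels[best]]] <- labels[drop]
        pool <- setdiff(pool, drop)
      }
    }
  }
  elbow_n <- if (length(f) >= 2) elbow_point(f, config$elbow_fraction) else 1L
  structure(list(technique_id = technique_id,
                 selected = labels[base],
                 selected_idx = base,
                 f = f,
                 pruned = pruned,
                 elbow_n = elbow_n),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %s: %d features selected, elbow at %d\n",
              x$technique_id, length(x$selected), x$elbow_n))
  for (i in seq_along(x$selected)) {
    cat(sprintf("  %2d. %-50s f = %.3f%s\n", i, x$selected[i], x$f[i],
                if (i == x$elbow_n) "  <- elbow" else ""))
  }
  invisible(x)
}

#' Elbow point of an accuracy curve
#'
#' Returns the smallest `n >= 1` for which the accuracy improvement
#' `f(n+1) - f(n)` falls below `elbow_fraction` of the curve's range
#' `max(f) - min(f)`. If no point qualifies, the full curve length is
#' returned.
#'
#' @param f numeric accuracy curve, `f[n]` the accuracy of the n-feature
#'   model; length at least 2.
#' @param elbow_fraction improvement threshold as a fraction of the range.
#' @return integer elbow position in `1..length(f)`.
#' @export
elbow_point <- function(f, elbow_fraction = 0.10) {
  if (length(f) < 2) stop("elbow_point needs an accuracy curve of length >= 2")
  threshold <- (max(f) - min(f)) * elbow_fraction
  hits <- which(diff(f) < threshold)
  if (length(hits)) hits[1] else length(f)
}

#' Minimal feature model of a selection trace
#'
#' The prefix of the forward-selection sequence up to the elbow point: the
#' smallest model that accounts for most of the attainable accuracy.
#'
#' @param trace a `selection_trace` from [forward_select()].
#' @return character vector of the selected feature labels.
#' @export
minimal_model <- function(trace) {
  stopifnot(inherits(trace, "selection_trace"))
  trace$selected[seq_len(trace$elbow_n)]
}

#' Write / read a selection trace as JSON
#' @param trace a `selection_trace`.
#' @param path file path.
#' @return `read_selection_trace` returns a `selection_trace`;
#'   `write_selection_trace` returns `path` invisibly.
#' @export
write_selection_trace <- function(trace, path) {
  stopifnot(inherits(trace, "selection_trace"))
  obj <- unclass(trace)
  obj <- c(list(schema = "limbclass-trace-1"), obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection_trace
#' @export
read_selection_trace <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "limbclass-trace-1")) {
    stop("not a limbclass selection trace")
  }
  structure(list(technique_id = obj$technique_id,
                 selected = as.character(obj$selected),
                 selected_idx = as.integer(obj$selected_idx),
                 f = as.numeric(obj$f),
                 pruned = as.list(obj$pruned),
                 elbow_n = as.integer(obj$elbow_n)),
            class = "selection_trace")
}
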