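#' Detect phases of variation in a set of waveforms
#'
#' Default detection strategy: center the trial-by-time matrix (subtract the
#' mean curve), take principal components over time, retain components in
#' eigenvalue order until cumulative explained variance reaches 95%, and
#' flag time point `t` when for any retained component the squared loading
#' at `t` is at least 50% of that component's maximum squared loading. The
#' returned mask is the union over retained components.
#'
#' The detector is a pluggable strategy: [build_support()] accepts any
#' function with this signature, so alternative phase detectors can be
#' swapped in without touching the memory-matrix bookkeeping.
#'
#' @param trials numeric matrix, one row per trial, 101 columns (time).
#' @param var_explained cumulative explained-variance cutoff for component
#'   retention.
#' @param loading_fraction fraction of a component's peak squared loading a
#'   time point must reach to be flagged.
#' @return integer vector of length 101 with entries 0/1.
#' @export
detect_variation_phases <- function(trials, var_explained = 0.95,
                                    loading_fraction = 0.50) {
  stopifnot(is.matrix(trials), ncol(trials) == cycle_length())
  if (nrow(trials) < 2) stop("phase detection needs at least 2 trials")
  centered <- sweep(trials, 2, colMeans(trials))
  total_var <- sum(centered^2)
  mask <- integer(cycle_length())
  if (total_var < 1e-12) {
    return(mask)
  }
  sv <- svd(centered)
  ev <- sv$d^2
  ev <- ev / sum(ev)
  keep <- seq_len(max(1L, which(cumsum(ev) >= var_explained)[1]))
  for (k in keep) {
    sq <- sv$v[, k]^2
    mask[sq >= loading_fraction * max(sq)] <- 1L
  }
  mask
}

#' Accumulate the memory matrix across resampled splits
#'
#' For each of `config$n_splits` splits, draws `config$subjects_per_group`
#' subjects from the ACL cohort and the same number from the control cohort
#' (subject level, so both limbs of a drawn subject enter), runs the phase
#' detector per signal on the assembled trials, and records the flagged time
#' points as 1-bits in a per-signal 101 x n_splits memory matrix. With the
#' default cohort sizes this reproduces the 200-trial subsets (50 operated +
#' 50 contralateral + 100 control limbs) of the full-scale analysis.
#'
#' @param dataset a `movement_dataset` (already symmetry-augmented for
#'   double-leg exercises; see [augment_symmetry()]).
#' @param config an [analysis_config()]; uses `n_splits`,
#'   `subjects_per_group` and the phase-stage seed.
#' @param detector phase-detection strategy, by default
#'   [detect_variation_phases()].
#' @return an object of class `support_set`: per signal the memory matrix
#'   (`bits`) and its row sums (`counts`, the support vector), plus
#'   `n_splits`.
#' @export
build_support <- function(dataset, config, detector = detect_variation_phases) {
  stopifnot(inherits(dataset, "movement_dataset"),
            inherits(config, "analysis_config"))
  meta <- dataset$meta
  acl_subjects <- unique(meta$subject_id[meta$class_label %in% c("ACL_OP", "ACL_NO_OP")])
  norm_subjects <- unique(meta$subject_id[meta$class_label == "NORM"])
  g <- config$subjects_per_group
  if (length(acl_subjects) < g) {
    stop(sprintf("insufficient subjects in ACL cohort: %d available, %d needed",
                 length(acl_subjects), g))
  }
  if (length(norm_subjects) < g) {
    stop(sprintf("insufficient subjects in NORM cohort: %d available, %d needed",
                 length(norm_subjects), g))
  }
  L <- cycle_length()
  bits <- lapply(dataset$signals, function(x) {
    matrix(0L, nrow = L, ncol = config$n_splits)
  })
  with_seed(config$seed_phases, {
    for (s in seq_len(config$n_splits)) {
      drawn <- c(sample(acl_subjects, g), sample(norm_subjects, g))
      cols <- which(meta$subject_id %in% drawn)
      for (sig in names(dataset$signals)) {
        mask <- detector(t(dataset$signals[[sig]][, cols, drop = FALSE]))
        bits[[sig]][, s] <- as.integer(mask)
      }
    }
  })
  per_signal <- lapply(names(bits), function(sig) {
    list(signal = sig, bits = bits[[sig]], counts = as.integer(rowSums(bits[[sig]])))
  })
  names(per_signal) <- names(bits)
  structure(list(signals = per_signal, n_splits = config$n_splits),
            class = "support_set")
}

#' Extract robust phases from a support vector
#'
#' A robust phase is a maximal contiguous run of time points that were
#' flagged in at least `support_threshold` of the splits (applied as
#' `>= ceiling(support_threshold * n_splits)`) and that spans at least
#' `min_span_fraction` of the movement cycle (5 samples at the default 5%).
#'
#' @param counts integer support vector of length 101 (or a `support_set`
#'   element with a `counts` field).
#' @param config an [analysis_config()].
#' @param n_splits number of splits the counts were accumulated over;
#'   defaults to `config$n_splits`.
#' @param signal_name carried into the returned phases.
#' @return data.frame with columns `signal`, `start_idx`, `end_idx`,
#'   `min_support` (one row per phase, ordered by start index); zero rows if
#'   no run qualifies.
#' @export
extract_robust_phases <- function(counts, config, n_splits = config$n_splits,
                                  signal_name = NA_character_) {
  if (is.list(counts) && !is.null(counts$counts)) {
    if (is.na(signal_name) && !is.null(counts$signal)) signal_name <- counts$signal
    counts <- counts$counts
  }
  stopifnot(length(counts) == cycle_length(), all(counts >= 0),
            all(counts <= n_splits))
  threshold <- ceiling(config$support_threshold * n_splits)
  min_span <- max(1L, as.integer(round(config$min_span_fraction * 100)))
  above <- counts >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_span)
  if (!length(keep)) {
    return(data.frame(signal = character(), start_idx = integer(),
                      end_idx = integer(), min_support = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    signal = signal_name,
    start_idx = starts[keep] - 1L,   # 0-based cycle index
    end_idx = ends[keep] - 1L,
    min_support = vapply(keep, function(k) {
      as.integer(min(counts[starts[k]:ends[k]]))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Robust phases for every signal of a support set
#'
#' @param support a `support_set` from [build_support()].
#' @param config an [analysis_config()].
#' @return data.frame of phases (columns `signal`, `start_idx`, `end_idx`,
#'   `min_support`), ordered by signal (dataset order) then start index.
#' @export
robust_phases <- function(support, config) {
  stopifnot(inherits(support, "support_set"))
  out <- lapply(support$signals, function(sv) {
    extract_robust_phases(sv$counts, config, n_splits = support$n_splits,
                          signal_name = sv$signal)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  rownames(res) <- NULL
  res
}

phase_label <- function(signal, start_idx, end_idx) {
  sprintf("%s (%d to %d%%)", signal, start_idx, end_idx)
}

#' Construct a feature matrix directly
#'
#' Mostly used internally by [build_feature_matrix()]; exposed for building
#' feature matrices from externally engineered features.
#'
#' @param values numeric matrix, features in rows, observations in columns.
#' @param labels feature labels (row names); defaults to existing row names.
#' @param meta observation metadata (`subject_id`, `limb_side`,
#'   `class_label`), one row per column of `values`.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(values, labels = rownames(values), meta) {
  stopifnot(is.matrix(values), length(labels) == nrow(values))
  features <- parse_feature_labels(as.character(labels))
  new_feature_matrix(values, features, meta)
}

new_feature_matrix <- function(values, features, meta) {
  stopifnot(nrow(values) == nrow(features), ncol(values) == nrow(meta))
  rownames(values) <- features$label
  structure(list(values = values, features = features, meta = meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d observations\n",
              nrow(x$values), ncol(x$values)))
  cat("  ", paste(utils::head(x$features$label, 4), collapse = "; "),
      if (nrow(x$features) > 4) "..." else "", "\n")
  invisible(x)
}

#' Build the phase-mean feature matrix
#'
#' One feature per (signal, robust phase): the mean of the observation's
#' waveform over the inclusive phase window, labelled
#' `"<signal> (<start> to <end>%)"`. For double-leg exercises the symmetry
#' signals must already be part of the dataset (see [augment_symmetry()]) so
#' that symmetry phases were discovered during support accumulation.
#'
#' @param dataset a `movement_dataset`.
#' @param phases data.frame of phases as returned by [robust_phases()].
#' @param config an [analysis_config()] (not consulted beyond validation;
#'   kept for interface symmetry).
#' @return a `feature_matrix` with `nrow(phases)` features and one column
#'   per observation.
#' @export
build_feature_matrix <- function(dataset, phases, config = NULL) {
  stopifnot(inherits(dataset, "movement_dataset"), is.data.frame(phases))
  if (!nrow(phases)) stop("no phases supplied; nothing to featurize")
  unknown <- setdiff(unique(phases$signal), names(dataset$signals))
  if (length(unknown)) {
    stop("phase references unknown signal: ", paste(unknown, collapse = ", "))
  }
  vals <- t(vapply(seq_len(nrow(phases)), function(i) {
    m <- dataset$signals[[phases$signal[i]]]
    rows <- (phases$start_idx[i]:phases$end_idx[i]) + 1L
    colMeans(m[rows, , drop = FALSE])
  }, numeric(n_observations(dataset))))
  features <- data.frame(
    label = phase_label(phases$signal, phases$start_idx, phases$end_idx),
    signal = phases$signal,
    start_idx = phases$start_idx,
    end_idx = phases$end_idx,
    stringsAsFactors = FALSE
  )
  new_feature_matrix(vals, features, dataset$meta)
}

#' Subset a feature matrix by feature
#' @param fm a `feature_matrix`.
#' @param idx integer/logical/character index over features (labels allowed).
#' @return a `feature_matrix` with the selected features.
#' @export
subset_features <- function(fm, idx) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.character(idx)) idx <- match(idx, fm$features$label)
  new_feature_matrix(fm$values[idx, , drop = FALSE],
                     fm$features[idx, , drop = FALSE], fm$meta)
}

#' Write / read phases as JSON
#' @param phases data.frame of phases.
#' @param path file path.
#' @return `read_phases` returns the phases data.frame; `write_phases`
#'   returns `path` invisibly.
#' @export
write_phases <- function(phases, path) {
  jsonlite::write_json(list(schema = "limbclass-phases-1", phases = phases),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phases
#' @export
read_phases <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "limbclass-phases-1")) {
    stop("not a limbclass phases file")
  }
  as.data.frame(obj$phases, stringsAsFactors = FALSE)
}
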