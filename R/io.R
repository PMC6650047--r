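DATASET_SCHEMA <- "#schema: limbclass-dataset-1"
FEATURES_SCHEMA <- "#schema: limbclass-features-1"

#' Write a movement dataset as a long-format delimited file
#'
#' One row per (observation, signal, time point), columns `subject_id`,
#' `limb`, `class`, `exercise`, `signal`, `t` (0..100) and `value`. Values
#' are written with 17 significant digits so that a write/load cycle
#' round-trips doubles bit-exactly. A schema-version line precedes the
#' header.
#'
#' @param dataset a `movement_dataset`.
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "movement_dataset"))
  meta <- dataset$meta
  n <- nrow(meta)
  L <- cycle_length()
  sigs <- names(dataset$signals)
  blocks <- lapply(sigs, function(s) {
    m <- dataset$signals[[s]]
    data.table::data.table(
      subject_id = rep(meta$subject_id, each = L),
      limb = rep(meta$limb_side, each = L),
      class = rep(meta$class_label, each = L),
      exercise = dataset$exercise_id,
      signal = s,
      t = rep(0:(L - 1L), times = n),
      value = sprintf("%.17g", as.vector(m))
    )
  })
  dt <- data.table::rbindlist(blocks)
  writeLines(DATASET_SCHEMA, path)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Load a movement dataset from a long-format delimited file
#'
#' Expects the format written by [write_dataset()]: columns `subject_id`,
#' `limb`, `class`, `exercise`, `signal`, `t`, `value`, with every
#' (observation, signal) pair contributing exactly 101 time points 0..100.
#'
#' @param path input file path.
#' @param exercise_mode `"single_leg"` or `"double_leg"`.
#' @return a validated `movement_dataset`.
#' @export
load_dataset <- function(path, exercise_mode = c("single_leg", "double_leg")) {
  exercise_mode <- match.arg(exercise_mode)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  skip <- if (identical(first, DATASET_SCHEMA)) 1L else 0L
  dt <- data.table::fread(path, skip = skip, header = TRUE,
                          colClasses = list(character = c("subject_id", "limb", "class",
                                                          "exercise", "signal"),
                                            integer = "t", numeric = "value"))
  need <- c("subject_id", "limb", "class", "exercise", "signal", "t", "value")
  if (!all(need %in% names(dt))) {
    stop("malformed dataset file: expected columns ", paste(need, collapse = ", "))
  }
  bad_class <- setdiff(unique(dt$class), limb_classes())
  if (length(bad_class)) {
    stop("unknown class: ", paste(bad_class, collapse = ", "))
  }
  L <- cycle_length()
  # observation key; class/exercise must be constant within it
  dt[, obs := paste(subject_id, limb, sep = "\r")]
  counts <- dt[, .N, by = .(obs, subject_id, limb, signal)]
  bad <- counts[N != L]
  if (nrow(bad)) {
    b <- bad[1]
    stop(sprintf("malformed waveform: subject %s limb %s signal '%s' has %d time points (expected %d)",
                 b$subject_id, b$limb, b$signal, b$N, L))
  }
  tchk <- dt[, .(ok = identical(sort(t), 0:(L - 1L))), by = .(subject_id, limb, signal)]
  if (any(!tchk$ok)) {
    b <- tchk[!(ok)][1]
    stop(sprintf("malformed waveform: subject %s limb %s signal '%s' has duplicated or out-of-range time points",
                 b$subject_id, b$limb, b$signal))
  }
  ncls <- dt[, .(k = data.table::uniqueN(class)), by = obs]
  if (any(ncls$k > 1)) {
    stop("duplicate observation: same (subject, limb) appears with conflicting class labels")
  }
  sigs <- unique(dt$signal)   # preserve writer's signal order
  per_obs <- dt[, .(k = data.table::uniqueN(signal)), by = obs]
  if (any(per_obs$k != length(sigs))) {
    stop("malformed dataset: observations carry differing signal sets")
  }
  # preserve the file's observation order so write -> load round-trips
  obs_meta <- unique(dt[, list(obs, subject_id, limb, class)])
  meta <- data.frame(subject_id = obs_meta$subject_id,
                     limb_side = obs_meta$limb,
                     class_label = obs_meta$class,
                     stringsAsFactors = FALSE)
  dt[, obs_ord := match(obs, obs_meta$obs)]
  dt[, sig_ord := match(signal, sigs)]
  data.table::setorder(dt, sig_ord, obs_ord, t)
  n <- nrow(obs_meta)
  signals <- lapply(seq_along(sigs), function(k) {
    matrix(dt[sig_ord == k, value], nrow = L, ncol = n)
  })
  names(signals) <- sigs
  movement_dataset(dt$exercise[1], exercise_mode, meta, signals)
}

#' Write / read a feature matrix as CSV
#'
#' The file has a schema-version line, then a header of three metadata
#' columns (`subject_id`, `limb_side`, `class_label`) followed by one column
#' per feature label; one row per observation. Values use 17 significant
#' digits (bit-exact round trip).
#'
#' @param fm a `feature_matrix` (see [build_feature_matrix()]).
#' @param path file path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns a `feature_matrix` (with phase bounds
#'   recovered from the labels).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  vals <- t(fm$values)
  dt <- data.table::data.table(
    subject_id = fm$meta$subject_id,
    limb_side = fm$meta$limb_side,
    class_label = fm$meta$class_label
  )
  for (j in seq_len(ncol(vals))) {
    dt[[fm$features$label[j]]] <- sprintf("%.17g", vals[, j])
  }
  writeLines(FEATURES_SCHEMA, path)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  skip <- if (identical(first, FEATURES_SCHEMA)) 1L else 0L
  dt <- data.table::fread(path, skip = skip, header = TRUE)
  labels <- setdiff(names(dt), c("subject_id", "limb_side", "class_label"))
  meta <- data.frame(subject_id = as.character(dt$subject_id),
                     limb_side = as.character(dt$limb_side),
                     class_label = as.character(dt$class_label),
                     stringsAsFactors = FALSE)
  values <- t(as.matrix(dt[, labels, with = FALSE]))
  rownames(values) <- labels
  parsed <- parse_feature_labels(labels)
  new_feature_matrix(values, parsed, meta)
}

# "<signal> (<a> to <b>%)" -> signal/start/end
parse_feature_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.*) \\((\\d+) to (\\d+)%\\)$", labels))
  sig <- vapply(m, function(x) if (length(x) == 4) x[2] else NA_character_, character(1))
  a <- vapply(m, function(x) if (length(x) == 4) as.integer(x[3]) else NA_integer_, integer(1))
  b <- vapply(m, function(x) if (length(x) == 4) as.integer(x[4]) else NA_integer_, integer(1))
  data.frame(label = labels, signal = sig, start_idx = a, end_idx = b,
             stringsAsFactors = FALSE)
}
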