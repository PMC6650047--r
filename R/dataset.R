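#' The three limb classes
#'
#' Fixed serialized names of the limb classes: the ACL-operated limb
#' (`ACL_OP`), the limb contralateral to the operated limb (`ACL_NO_OP`),
#' and a healthy-control limb (`NORM`).
#'
#' @return character vector of the three class names, in canonical order.
#' @export
limb_classes <- function() c("ACL_OP", "ACL_NO_OP", "NORM")

#' Number of samples per movement cycle
#'
#' Waveforms are landmark-registered and time-normalized to 101 samples,
#' indexed 0..100 as percent of the movement cycle.
#' @return 101L
#' @export
cycle_length <- function() 101L

#' Construct a movement dataset
#'
#' A movement dataset holds one trial per limb per subject for one exercise:
#' per-observation metadata plus a set of named signals, each stored as a
#' `101 x n` matrix whose columns align with the metadata rows.
#'
#' @param exercise_id short exercise identifier (e.g. `"DLDJ"`).
#' @param exercise_mode `"single_leg"` or `"double_leg"`; double-leg
#'   exercises additionally admit inter-limb symmetry signals.
#' @param meta data.frame with columns `subject_id`, `limb_side`
#'   (`"left"`/`"right"`) and `class_label` (see [limb_classes()]); one row
#'   per limb observation.
#' @param signals named list of `101 x nrow(meta)` numeric matrices.
#' @return an object of class `movement_dataset`.
#' @export
movement_dataset <- function(exercise_id, exercise_mode, meta, signals) {
  exercise_mode <- match.arg(exercise_mode, c("single_leg", "double_leg"))
  stopifnot(is.data.frame(meta),
            all(c("subject_id", "limb_side", "class_label") %in% names(meta)),
            is.list(signals), length(signals) >= 1, !is.null(names(signals)))
  meta <- data.frame(
    subject_id = as.character(meta$subject_id),
    limb_side = as.character(meta$limb_side),
    class_label = as.character(meta$class_label),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(unique(meta$class_label), limb_classes())
  if (length(bad)) {
    stop("unknown class: ", paste(bad, collapse = ", "))
  }
  if (!all(meta$limb_side %in% c("left", "right"))) {
    stop("limb_side must be 'left' or 'right'")
  }
  n <- nrow(meta)
  for (s in names(signals)) {
    m <- signals[[s]]
    if (!is.matrix(m) || nrow(m) != cycle_length() || ncol(m) != n) {
      stop(sprintf("signal '%s' must be a %d x %d matrix", s, cycle_length(), n))
    }
    if (!all(is.finite(m))) {
      stop(sprintf("signal '%s' contains non-finite values", s))
    }
  }
  structure(
    list(exercise_id = as.character(exercise_id),
         exercise_mode = exercise_mode,
         meta = meta,
         signals = signals),
    class = "movement_dataset"
  )
}

#' @export
print.movement_dataset <- function(x, ...) {
  tab <- table(factor(x$meta$class_label, levels = limb_classes()))
  cat(sprintf("<movement_dataset> exercise %s (%s)\n", x$exercise_id, x$exercise_mode))
  cat(sprintf("  %d observations: %s\n", nrow(x$meta),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  %d signals: %s\n", length(x$signals),
              paste(utils::head(names(x$signals), 6), collapse = ", ")))
  invisible(x)
}

#' Number of observations in a dataset
#' @param dataset a `movement_dataset`.
#' @return integer count of limb observations.
#' @export
n_observations <- function(dataset) nrow(dataset$meta)

#' Validate the subject/limb structure of a dataset
#'
#' Checks the pairing rules of the study layout without raising: every ACL
#' subject must contribute exactly one `ACL_OP` and one `ACL_NO_OP`
#' observation on opposite limb sides; every control subject exactly two
#' `NORM` observations, one per limb side; no subject may mix cohorts and no
#' (subject, limb) pair may repeat.
#'
#' @param dataset a `movement_dataset`.
#' @return data.frame with columns `subject_id`, `rule`, `message`; zero
#'   rows if and only if the dataset satisfies the layout invariants.
#' @export
validate_structure <- function(dataset) {
  stopifnot(inherits(dataset, "movement_dataset"))
  meta <- dataset$meta
  out <- list()
  flag <- function(subject, rule, msg) {
    out[[length(out) + 1L]] <<- data.frame(
      subject_id = subject, rule = rule, message = msg, stringsAsFactors = FALSE
    )
  }
  key <- paste(meta$subject_id, meta$limb_side)
  dup <- unique(meta$subject_id[duplicated(key)])
  for (s in dup) flag(s, "duplicate_limb", "duplicated (subject, limb side) observation")
  for (s in unique(meta$subject_id)) {
    cls <- meta$class_label[meta$subject_id == s]
    sides <- meta$limb_side[meta$subject_id == s]
    is_norm <- any(cls == "NORM")
    is_acl <- any(cls %in% c("ACL_OP", "ACL_NO_OP"))
    if (is_norm && is_acl) {
      flag(s, "mixed_cohort", "subject carries both NORM and ACL observations")
      next
    }
    if (is_norm) {
      if (length(cls) != 2 || !setequal(sides, c("left", "right"))) {
        flag(s, "norm_pairing",
             "NORM subject must contribute exactly one left and one right limb")
      }
    } else {
      missing <- setdiff(c("ACL_OP", "ACL_NO_OP"), cls)
      if (length(missing) || length(cls) != 2) {
        flag(s, "acl_pairing",
             sprintf("ACL subject must contribute one ACL_OP and one ACL_NO_OP observation%s",
                     if (length(missing)) paste0("; missing ", paste(missing, collapse = ", ")) else ""))
      } else if (sides[1] == sides[2]) {
        flag(s, "acl_pairing", "ACL_OP and ACL_NO_OP must be on opposite limb sides")
      }
    }
  }
  if (!length(out)) {
    data.frame(subject_id = character(), rule = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' Subset a dataset by observation index
#' @param dataset a `movement_dataset`.
#' @param idx integer or logical index over observations.
#' @return a `movement_dataset` with the selected observations.
#' @export
subset_observations <- function(dataset, idx) {
  movement_dataset(
    dataset$exercise_id, dataset$exercise_mode,
    dataset$meta[idx, , drop = FALSE],
    lapply(dataset$signals, function(m) m[, idx, drop = FALSE])
  )
}

#' Append inter-limb symmetry signals
#'
#' For double-leg exercises, derives one symmetry signal per source signal as
#' the observation's own waveform minus the same subject's contralateral-limb
#' waveform (left - right for left-leg observations and vice versa). The
#' derived signals are named `"<signal> symmetry"` and take part in phase
#' detection like any other signal, so symmetry phases are discovered rather
#' than imposed. Single-leg datasets are returned unchanged.
#'
#' @param dataset a `movement_dataset`.
#' @return a `movement_dataset`, augmented when `exercise_mode` is
#'   `"double_leg"`.
#' @export
augment_symmetry <- function(dataset) {
  stopifnot(inherits(dataset, "movement_dataset"))
  if (dataset$exercise_mode != "double_leg") {
    return(dataset)
  }
  meta <- dataset$meta
  # index of the contralateral observation for every column
  contra <- vapply(seq_len(nrow(meta)), function(i) {
    j <- which(meta$subject_id == meta$subject_id[i] & meta$limb_side != meta$limb_side[i])
    if (length(j) != 1) {
      stop(sprintf("subject %s lacks a unique contralateral observation; run validate_structure()",
                   meta$subject_id[i]))
    }
    j
  }, integer(1))
  sym <- lapply(dataset$signals, function(m) m - m[, contra, drop = FALSE])
  names(sym) <- paste(names(dataset$signals), "symmetry")
  movement_dataset(dataset$exercise_id, dataset$exercise_mode, meta,
                   c(dataset$signals, sym))
}
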