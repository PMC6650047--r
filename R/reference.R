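#' Reference results of the original motion-capture study
#'
#' The framework was developed on a motion-capture study of 156
#' ACL-reconstructed athletes and 62 healthy controls performing eight
#' jumping, hopping and change-of-direction exercises. The raw waveforms of
#' that study are not deposited, but its reported minimal-feature-model
#' confusion matrices and performance summaries are shipped here as
#' plain-text tables: they serve as arithmetic inputs for the evaluation
#' module (sensitivities, binary collapse and cross-exercise averages are
#' recomputed from the printed counts, not copied).
#'
#' @param exercise one of `reference_exercises()`; for
#'   `reference_confusion`, the exercise whose 3x3 matrix to return.
#' @return `reference_confusion()` returns a 3x3 integer matrix (rows
#'   predicted, columns actual); `reference_performance()` the per-exercise
#'   summary table; `reference_exercises()` the exercise identifiers.
#' @export
reference_confusion <- function(exercise) {
  counts <- utils::read.csv(reference_file("reference_confusion_counts.csv"),
                            stringsAsFactors = FALSE)
  exercise <- match.arg(exercise, unique(counts$exercise))
  sub <- counts[counts$exercise == exercise, ]
  cls <- limb_classes()
  m <- matrix(0L, 3, 3, dimnames = list(predicted = cls, actual = cls))
  for (i in seq_len(nrow(sub))) {
    m[sub$predicted[i], sub$actual[i]] <- sub$count[i]
  }
  m
}

#' @rdname reference_confusion
#' @export
reference_performance <- function() {
  utils::read.csv(reference_file("reference_performance.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_confusion
#' @export
reference_exercises <- function() {
  unique(utils::read.csv(reference_file("reference_performance.csv"),
                         stringsAsFactors = FALSE)$exercise)
}

reference_file <- function(name) {
  path <- system.file("extdata", name, package = "limbclass")
  if (!nzchar(path)) stop("reference table not found: ", name)
  path
}
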