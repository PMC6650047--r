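#' Accumulate a confusion matrix from prediction records
#'
#' Orientation is fixed: rows are the predicted class, columns the actual
#' class, both in the canonical order of [limb_classes()].
#'
#' @param records data.frame with `actual` and `predicted` columns (class
#'   labels), e.g. the `records` field of a `technique_result`.
#' @return 3x3 integer matrix of counts.
#' @export
accumulate_confusion <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("actual", "predicted") %in% names(records)))
  cls <- limb_classes()
  m <- table(factor(records$predicted, levels = cls),
             factor(records$actual, levels = cls))
  out <- matrix(as.integer(m), nrow = 3, dimnames = list(predicted = cls, actual = cls))
  out
}

#' Per-class sensitivity of a confusion matrix
#'
#' Sensitivity (recall) of class `c` is the diagonal count divided by the
#' column total of `c` — the actual-class denominator. Use [percent()] for
#' the half-up integer-percent convention of reported values.
#'
#' @param cm 3x3 confusion matrix, rows predicted, columns actual.
#' @return named numeric vector of per-class sensitivities (fractions).
#' @export
class_sensitivity <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == 3, ncol(cm) == 3)
  totals <- colSums(cm)
  zero <- totals == 0
  if (any(zero)) {
    stop("no actual observations of class: ",
         paste(limb_classes()[zero], collapse = ", "))
  }
  stats::setNames(diag(cm) / totals, limb_classes())
}

#' Collapse a limb-level confusion matrix to the group level
#'
#' Merges the two ACL classes on both axes, yielding a 2x2 (ACL, NORM)
#' matrix. The pooled binary accuracy counts every within-ACL prediction
#' (including operated/contralateral confusions) as correct, so it can only
#' exceed or match the multiclass accuracy of the same records.
#'
#' @param cm 3x3 confusion matrix, rows predicted, columns actual.
#' @return list with `counts` (2x2 matrix) and `accuracy` (pooled fraction).
#' @export
collapse_to_group <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == 3, ncol(cm) == 3)
  acl <- c("ACL_OP", "ACL_NO_OP")
  counts <- matrix(c(sum(cm[acl, acl]), sum(cm["NORM", acl]),
                     sum(cm[acl, "NORM"]), cm["NORM", "NORM"]),
                   nrow = 2, dimnames = list(predicted = c("ACL", "NORM"),
                                             actual = c("ACL", "NORM")))
  list(counts = counts, accuracy = sum(diag(counts)) / sum(counts))
}

#' Multiclass accuracy of a confusion matrix
#' @param cm square confusion matrix.
#' @return fraction of diagonal counts.
#' @export
confusion_accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' Is a model meaningful against the guess baseline?
#'
#' A model is meaningful when its lowest per-split accuracy is strictly
#' greater than the best guess (the highest accuracy ever achieved by
#' uniform random class assignment over the same splits).
#'
#' @param result a `technique_result` (or any list with a
#'   `per_split_accuracy` field).
#' @param best_guess the `best_guess` from [guess_baseline()].
#' @return logical.
#' @export
meaningfulness <- function(result, best_guess) {
  acc <- result$per_split_accuracy
  stopifnot(length(acc) >= 1)
  min(acc) > best_guess
}

#' Subject-level consistency: never-misclassified members per class
#'
#' A subject counts as a "true" member of a class if every test-set
#' prediction ever made for that subject's observations of that class was
#' correct (for controls this requires both limbs; a single error
#' disqualifies). The denominator is the number of subjects of that class
#' appearing in at least one test set.
#'
#' @param records prediction records (data.frame with `subject_id`,
#'   `actual`, `predicted`).
#' @return list with `per_subject` (data.frame: subject_id, class,
#'   n_appearances, n_misclassified) and `true_fraction` (named vector per
#'   class).
#' @export
subject_consistency <- function(records) {
  stopifnot(nrow(records) >= 1)
  key <- paste(records$subject_id, records$actual, sep = "\r")
  app <- tapply(records$predicted, key, length)
  mis <- tapply(records$predicted != records$actual, key, sum)
  parts <- strsplit(names(app), "\r", fixed = TRUE)
  per_subject <- data.frame(
    subject_id = vapply(parts, `[`, character(1), 1),
    class = vapply(parts, `[`, character(1), 2),
    n_appearances = as.integer(app),
    n_misclassified = as.integer(mis),
    stringsAsFactors = FALSE
  )
  true_fraction <- vapply(limb_classes(), function(cl) {
    sub <- per_subject[per_subject$class == cl, ]
    if (!nrow(sub)) return(NA_real_)
    mean(sub$n_misclassified == 0)
  }, numeric(1))
  list(per_subject = per_subject, true_fraction = true_fraction)
}

#' Final k-fold re-validation of a minimal feature model
#'
#' Re-evaluates a (minimal) feature model with a subject-subsampled k-fold
#' design: each fold draws a class-balanced test set of
#' `config$kfold_test_per_class` subjects per class and a class-balanced,
#' disjoint training set of `config$kfold_train_per_class` subjects per
#' class. Every subject contributes exactly one observation in its assigned
#' class role — controls enter with one randomly chosen limb, and ACL
#' subjects serve either the operated-limb or the contralateral-limb role
#' (disjoint subject sets) — so a fold's test accuracy has resolution
#' `1 / (3 * kfold_test_per_class)` (1/18 at the full-scale 52/6 layout).
#' Control test subjects are drawn without replacement across folds as far
#' as cohort size allows.
#'
#' @param features a `feature_matrix`, typically restricted to the minimal
#'   model via [subset_features()].
#' @param technique_id one of [technique_panel()].
#' @param config an [analysis_config()]; uses the k-fold layout fields and
#'   the k-fold stage seed.
#' @return list with `per_fold_accuracy`, `mean`, `sd`, `lowest`,
#'   `records`, and `folds` (per-fold train/test subject sets).
#' @export
kfold_validate <- function(features, technique_id, config) {
  stopifnot(inherits(features, "feature_matrix"))
  meta <- features$meta
  x_all <- t(features$values)
  n_test <- config$kfold_test_per_class
  n_train <- config$kfold_train_per_class
  k <- config$kfold_folds
  norm_subjects <- unique(meta$subject_id[meta$class_label == "NORM"])
  acl_subjects <- unique(meta$subject_id[meta$class_label %in% c("ACL_OP", "ACL_NO_OP")])
  if (length(norm_subjects) < n_train + n_test) {
    stop(sprintf("insufficient NORM subjects: %d available, %d needed per fold",
                 length(norm_subjects), n_train + n_test))
  }
  if (length(acl_subjects) < 2 * (n_train + n_test)) {
    stop(sprintf("insufficient ACL subjects: %d available, %d needed per fold",
                 length(acl_subjects), 2 * (n_train + n_test)))
  }
  # one observation per (subject, class role)
  obs_of <- function(subjects, class) {
    which(meta$subject_id %in% subjects & meta$class_label == class)
  }
  with_seed(config$seed_kfold, {
    # control test subjects disjoint across folds while counts allow
    norm_rotation <- sample(norm_subjects)
    recs <- list()
    folds <- list()
    acc <- numeric(k)
    for (fold in seq_len(k)) {
      take <- ((fold - 1L) * n_test + seq_len(n_test) - 1L) %% length(norm_rotation) + 1L
      norm_test <- norm_rotation[take]
      norm_train <- sample(setdiff(norm_subjects, norm_test), n_train)
      acl_perm <- sample(acl_subjects)
      op_train <- acl_perm[seq_len(n_train)]
      noop_train <- acl_perm[n_train + seq_len(n_train)]
      op_test <- acl_perm[2 * n_train + seq_len(n_test)]
      noop_test <- acl_perm[2 * n_train + n_test + seq_len(n_test)]
      pick_one_limb <- function(idx) {
        # controls have two limbs; keep one at random per subject
        split_idx <- split(idx, meta$subject_id[idx])
        vapply(split_idx, function(i) if (length(i) > 1) sample(i, 1) else i,
               integer(1))
      }
      folds[[fold]] <- list(train_subjects = c(norm_train, op_train, noop_train),
                            test_subjects = c(norm_test, op_test, noop_test))
      tr_idx <- c(pick_one_limb(obs_of(norm_train, "NORM")),
                  obs_of(op_train, "ACL_OP"),
                  obs_of(noop_train, "ACL_NO_OP"))
      te_idx <- c(pick_one_limb(obs_of(norm_test, "NORM")),
                  obs_of(op_test, "ACL_OP"),
                  obs_of(noop_test, "ACL_NO_OP"))
      xtr <- x_all[tr_idx, , drop = FALSE]
      xte <- x_all[te_idx, , drop = FALSE]
      if (config$normalization == "zscore") {
        z <- zscore_fit_apply(xtr, xte)
        xtr <- z$train
        xte <- z$test
      }
      seed <- derive_seed(config$seed_kfold, paste0(technique_id, ":", fold))
      pred <- train_predict(technique_id, xtr, meta$class_label[tr_idx], xte,
                            seed = seed)
      actual <- meta$class_label[te_idx]
      acc[fold] <- mean(pred == actual)
      recs[[fold]] <- data.frame(split = fold,
                                 subject_id = meta$subject_id[te_idx],
                                 limb_side = meta$limb_side[te_idx],
                                 actual = actual, predicted = pred,
                                 stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    list(per_fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
         lowest = min(acc), records = records, folds = folds)
  })
}
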