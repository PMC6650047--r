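toy_records <- function() {
  # 3 subjects: one flawless, one mixed, one always wrong
  data.frame(
    split = rep(1:2, each = 3),
    subject_id = rep(c("s1", "s2", "s3"), 2),
    limb_side = "left",
    actual = rep(c("ACL_OP", "ACL_OP", "ACL_OP"), 2),
    predicted = c("ACL_OP", "ACL_OP", "NORM", "ACL_OP", "NORM", "NORM"),
    stringsAsFactors = FALSE
  )
}

test_that("confusion accumulation conserves records and fixes orientation", {
  recs <- data.frame(actual = c(rep("ACL_OP", 4), rep("NORM", 6)),
                     predicted = c(rep("ACL_OP", 3), "NORM", rep("NORM", 6)),
                     stringsAsFactors = FALSE)
  cm <- accumulate_confusion(recs)
  expect_identical(sum(cm), nrow(recs))
  expect_identical(cm["ACL_OP", "ACL_OP"], 3L)      # rows = predicted
  expect_identical(cm["NORM", "ACL_OP"], 1L)        # columns = actual
  expect_identical(cm["ACL_OP", "NORM"], 0L)

  all_right <- data.frame(actual = rep(limb_classes(), 4),
                          predicted = rep(limb_classes(), 4))
  cm2 <- accumulate_confusion(all_right)
  expect_identical(sum(diag(cm2)), 12L)
  expect_identical(sum(cm2) - sum(diag(cm2)), 0L)
})

test_that("sensitivities equal an independent per-record tally", {
  set.seed(64)
  recs <- data.frame(
    actual = sample(limb_classes(), 500, replace = TRUE),
    predicted = sample(limb_classes(), 500, replace = TRUE),
    stringsAsFactors = FALSE
  )
  sens <- class_sensitivity(accumulate_confusion(recs))
  for (cl in limb_classes()) {
    tally <- mean(recs$predicted[recs$actual == cl] == cl)
    expect_equal(unname(sens[cl]), tally)
  }
  ident <- diag(c(5L, 7L, 9L))
  dimnames(ident) <- list(limb_classes(), limb_classes())
  expect_equal(unname(class_sensitivity(ident)), c(1, 1, 1))
})

test_that("group collapse can only improve on multiclass accuracy", {
  set.seed(65)
  for (i in 1:50) {
    cm <- matrix(sample(0:40, 9, replace = TRUE), 3,
                 dimnames = list(limb_classes(), limb_classes()))
    if (sum(cm) == 0) next
    g <- collapse_to_group(cm)
    expect_gte(g$accuracy, confusion_accuracy(cm))
    expect_identical(sum(g$counts), sum(cm))
  }
})

test_that("meaningfulness requires strictly beating the best guess", {
  res <- list(per_split_accuracy = c(0.45, 0.52, 0.61))
  expect_true(meaningfulness(res, 0.42))
  expect_false(meaningfulness(res, 0.45))   # boundary: equal is not meaningful
  expect_false(meaningfulness(res, 0.50))
})

test_that("subject consistency counts never-misclassified members strictly", {
  out <- subject_consistency(toy_records())
  expect_equal(unname(out$true_fraction["ACL_OP"]), 1 / 3)
  s2 <- out$per_subject[out$per_subject$subject_id == "s2", ]
  expect_identical(s2$n_appearances, 2L)
  expect_identical(s2$n_misclassified, 1L)   # one error in 2 appearances disqualifies
  expect_true(all(out$per_subject$n_misclassified <= out$per_subject$n_appearances))
})

test_that("k-fold validation: resolution, leakage and role disjointness", {
  d <- generate_dataset(generator_spec(n_norm_subjects = 20, n_acl_subjects = 30,
                                       signal_specs = default_signal_specs()[1:3],
                                       rng_seed = 15))
  cfg <- reduced_config(n_splits = 5, subjects_per_group = 10,
                        kfold_folds = 5, kfold_train_per_class = 10,
                        kfold_test_per_class = 3, rng_seed = 15)
  sup <- build_support(d, cfg)
  fm <- build_feature_matrix(d, robust_phases(sup, cfg), cfg)
  kv <- kfold_validate(fm, "discriminant", cfg)
  expect_length(kv$per_fold_accuracy, 5)
  # per-fold accuracy is a multiple of 1 / (3 * test_per_class)
  res <- 1 / 9
  expect_true(all(abs(kv$per_fold_accuracy / res - round(kv$per_fold_accuracy / res)) < 1e-9))
  expect_equal(kv$mean, mean(kv$per_fold_accuracy))
  expect_equal(kv$lowest, min(kv$per_fold_accuracy))
  for (fold in unique(kv$records$split)) {
    recs <- kv$records[kv$records$split == fold, ]
    expect_identical(nrow(recs), 9L)
    expect_identical(as.vector(table(factor(recs$actual, limb_classes()))), rep(3L, 3))
    # one observation per test subject: no subject straddles class roles
    expect_false(any(duplicated(recs$subject_id)))
  }
  for (f in kv$folds) {
    expect_length(intersect(f$train_subjects, f$test_subjects), 0)
    expect_false(any(duplicated(f$train_subjects)))
  }
})

test_that("k-fold validation errors when cohorts are too small", {
  d <- generate_dataset(tiny_spec(n_norm = 6, n_acl = 10, seed = 1))
  cfg <- reduced_config(kfold_train_per_class = 10, kfold_test_per_class = 3)
  sup <- build_support(d, reduced_config(n_splits = 3, subjects_per_group = 4, rng_seed = 2))
  fm <- build_feature_matrix(d, robust_phases(sup, reduced_config(n_splits = 3, subjects_per_group = 4, rng_seed = 2)), cfg)
  expect_error(kfold_validate(fm, "discriminant", cfg), "insufficient")
})
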