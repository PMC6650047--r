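test_that("split plans match the study partition sizes and are subject-exclusive", {
  meta <- make_meta(62, 156)
  cfg <- analysis_config(n_splits = 5, rng_seed = 10)
  plans <- plan_splits(meta, cfg)
  expect_length(plans, 5)
  for (p in plans) {
    tr <- meta[meta$subject_id %in% p$train_subjects, ]
    te <- meta[meta$subject_id %in% p$test_subjects, ]
    tr_tab <- table(factor(tr$class_label, levels = limb_classes()))
    te_tab <- table(factor(te$class_label, levels = limb_classes()))
    expect_true(all(abs(tr_tab - 88) <= 4))   # "around 88 trials from each class"
    expect_true(all(abs(te_tab - 30) <= 2))   # "around 30 trials from each class"
    # every subject in exactly one partition
    all_sub <- unique(meta$subject_id)
    membership <- cbind(all_sub %in% p$train_subjects,
                        all_sub %in% p$test_subjects,
                        all_sub %in% p$holdout_subjects)
    expect_true(all(rowSums(membership) == 1))
  }
})

test_that("no subject ever straddles train and test in any plan", {
  meta <- make_meta(20, 50)
  cfg <- reduced_config(n_splits = 25, rng_seed = 3)
  plans <- plan_splits(meta, cfg)
  for (p in plans) {
    expect_length(intersect(p$train_subjects, p$test_subjects), 0)
    expect_length(intersect(p$train_subjects, p$holdout_subjects), 0)
    expect_length(intersect(p$test_subjects, p$holdout_subjects), 0)
  }
})

test_that("z-scoring uses training statistics and guards zero-variance features", {
  train <- cbind(a = c(8, 10, 12), b = c(1, 1, 1))
  test <- cbind(a = c(10, 14), b = c(5, 7))
  z <- zscore_fit_apply(train, test)
  expect_equal(unname(z$test[1, "a"]), 0)      # equals the training mean
  expect_equal(unname(z$test[2, "a"]), 2)      # (14 - 10) / sd 2
  expect_true(z$constant[["b"]])
  expect_true(all(z$train[, "b"] == 0) && all(z$test[, "b"] == 0))
})

test_that("distance2mean assigns an exact class mean to that class", {
  xtr <- rbind(c(0, 0), c(0.2, 0), c(5, 5), c(5.2, 5), c(-5, 2), c(-5.2, 2))
  ytr <- c("ACL_OP", "ACL_OP", "ACL_NO_OP", "ACL_NO_OP", "NORM", "NORM")
  xte <- rbind(c(0.1, 0), c(5.1, 5), c(-5.1, 2))
  expect_identical(train_predict("distance2mean", xtr, ytr, xte),
                   c("ACL_OP", "ACL_NO_OP", "NORM"))
})

test_that("correlation2mean requires at least two features", {
  xtr <- matrix(rnorm(12), ncol = 1)
  ytr <- rep(limb_classes(), 4)
  expect_error(train_predict("correlation2mean", xtr, ytr, xtr), ">=2 features")
})

test_that("every technique separates well-separated single-feature classes", {
  set.seed(31)
  centers <- c(ACL_OP = -5, ACL_NO_OP = 0, NORM = 5)
  ytr <- rep(limb_classes(), each = 50)
  xtr <- matrix(rnorm(150, centers[ytr], 0.5), ncol = 1)
  yte <- rep(limb_classes(), each = 20)
  xte <- matrix(rnorm(60, centers[yte], 0.5), ncol = 1)
  for (t_id in setdiff(technique_panel(), "correlation2mean")) {
    pred <- train_predict(t_id, xtr, ytr, xte, seed = 4)
    expect_gte(mean(pred == yte), 0.95)
  }
  expect_error(train_predict("nonsense", xtr, ytr, xte), "unknown technique")
})

test_that("technique evaluation keeps holdout untouched and books records correctly", {
  meta <- make_meta(16, 40)
  fm <- make_shifted_features(meta, shifts = c(3, 0), noise_sd = 0.25, seed = 2)
  cfg <- reduced_config(n_splits = 8, rng_seed = 5)
  plans <- plan_splits(fm, cfg)
  res <- evaluate_technique(fm, "discriminant", plans, cfg)
  expect_length(res$per_split_accuracy, 8)
  expect_true(all(res$per_split_accuracy >= 0 & res$per_split_accuracy <= 1))
  expect_equal(res$mean_accuracy, mean(res$per_split_accuracy))
  n_test <- sum(vapply(plans, function(p) sum(fm$meta$subject_id %in% p$test_subjects),
                       numeric(1)))
  expect_identical(nrow(res$records), as.integer(n_test))
  # records only ever reference test subjects of their split
  for (p in plans) {
    recs <- res$records[res$records$split == p$split_index, ]
    expect_true(all(recs$subject_id %in% p$test_subjects))
  }
  # a strongly separating feature drives accuracy high
  expect_gte(res$mean_accuracy, 0.95)
})

test_that("evaluation is deterministic under a fixed seed", {
  meta <- make_meta(12, 30)
  fm <- make_shifted_features(meta, shifts = c(1, 0.5), seed = 3)
  cfg <- reduced_config(n_splits = 6, rng_seed = 11)
  plans <- plan_splits(fm, cfg)
  r1 <- evaluate_technique(fm, "random_forest", plans, cfg)
  r2 <- evaluate_technique(fm, "random_forest", plans, cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(plan_splits(fm, cfg), plans)
})

test_that("class-independent features give chance-level accuracy", {
  meta <- make_meta(16, 40)
  fm <- make_shifted_features(meta, shifts = c(0, 0, 0), noise_sd = 1, seed = 9)
  cfg <- reduced_config(n_splits = 10, rng_seed = 21)
  plans <- plan_splits(fm, cfg)
  res <- evaluate_technique(fm, "discriminant", plans, cfg)
  n_te <- sum(fm$meta$subject_id %in% plans[[1]]$test_subjects)
  ci <- 1.96 * sqrt((1 / 3) * (2 / 3) / n_te)
  expect_lt(abs(res$mean_accuracy - 1 / 3), ci)
})

test_that("ranking reports raw and z-scored accuracies and an argmax winner", {
  meta <- make_meta(14, 35)
  fm <- make_shifted_features(meta, shifts = c(2, 0), noise_sd = 0.4, seed = 6)
  cfg <- reduced_config(n_splits = 4, rng_seed = 8)
  plans <- plan_splits(fm, cfg)
  rk <- rank_techniques(fm, plans, cfg,
                        techniques = c("discriminant", "distance2mean", "naive_bayes"))
  expect_identical(names(rk$table), c("technique", "accuracy_raw", "accuracy_zscore"))
  expect_true(all(is.finite(rk$table$accuracy_raw)))
  win_acc <- rk$table$accuracy_zscore[rk$table$technique == rk$winner]
  expect_true(all(win_acc >= rk$table$accuracy_zscore))
})

test_that("tree techniques beat the linear discriminant on XOR-like geometry", {
  set.seed(77)
  meta <- make_meta(20, 50)
  n <- nrow(meta)
  cls <- meta$class_label
  # XOR arms for the two ACL classes, NORM at the center: no linear separation
  arm <- sample(c(-1, 1), n, replace = TRUE)
  x1 <- ifelse(cls == "ACL_OP", arm * 2,
               ifelse(cls == "ACL_NO_OP", arm * 2, 0)) + rnorm(n, 0, 0.3)
  x2 <- ifelse(cls == "ACL_OP", arm * 2,
               ifelse(cls == "ACL_NO_OP", -arm * 2, 0)) + rnorm(n, 0, 0.3)
  vals <- rbind(x1, x2)
  rownames(vals) <- c("f1 (0 to 100%)", "f2 (0 to 100%)")
  fm <- feature_matrix(vals, meta = meta)
  cfg <- reduced_config(n_splits = 6, rng_seed = 14)
  plans <- plan_splits(fm, cfg)
  tree <- evaluate_technique(fm, "random_forest", plans, cfg)
  lin <- evaluate_technique(fm, "discriminant", plans, cfg)
  expect_gt(tree$mean_accuracy, lin$mean_accuracy + 0.1)
})

test_that("guess baseline: best guess dominates the mean and is seed-stable", {
  meta <- make_meta(62, 156)
  cfg <- analysis_config(n_splits = 50, rng_seed = 17)
  plans <- plan_splits(meta, cfg)
  g <- guess_baseline(meta, plans, cfg)
  expect_length(g$per_split_accuracy, 50)
  expect_gte(g$best_guess, mean(g$per_split_accuracy))
  expect_lt(abs(mean(g$per_split_accuracy) - 1 / 3), 0.05)
  expect_identical(guess_baseline(meta, plans, cfg), g)
})
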