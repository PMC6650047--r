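#' The supervised-learning technique panel
#'
#' Panel order is also the deterministic tie-break order used by
#' [rank_techniques()]. All fits use library defaults; no hyperparameter
#' search is performed anywhere in the framework.
#'
#' @return character vector of technique identifiers.
#' @export
technique_panel <- function() {
  c("regression", "discriminant", "knn", "naive_bayes", "decision_tree",
    "random_forest", "svm", "neural_network", "correlation2mean",
    "distance2mean")
}

#' Plan subject-level shuffle splits
#'
#' For every split, control (NORM) subjects are partitioned into
#' train/test/holdout by the configured fractions (70/25/5% by default,
#' rounded down to whole subjects; the remainder is held out). ACL subjects
#' are then drawn so that each class's observation count in train and test
#' matches the NORM observation count per partition (a control subject
#' contributes two NORM observations, an ACL subject one observation per ACL
#' class); remaining ACL subjects are held out. All assignment is at subject
#' level, so both limbs of a subject always land in the same partition. With
#' the default study layout this yields about 86 training and 30 test
#' trials per class. The holdout partition carries no computation; its role
#' is to increase the interchange of trials across splits.
#'
#' @param meta observation metadata: a data.frame with `subject_id` and
#'   `class_label` columns, or a `movement_dataset` / `feature_matrix`.
#' @param config an [analysis_config()].
#' @return list of split plans; each plan has `split_index` and character
#'   vectors `train_subjects`, `test_subjects`, `holdout_subjects`.
#' @export
plan_splits <- function(meta, config) {
  meta <- as_obs_meta(meta)
  stopifnot(inherits(config, "analysis_config"))
  norm_subjects <- unique(meta$subject_id[meta$class_label == "NORM"])
  acl_subjects <- unique(meta$subject_id[meta$class_label %in% c("ACL_OP", "ACL_NO_OP")])
  fr <- config$split_fractions
  n_norm <- length(norm_subjects)
  n_train_norm <- floor(fr[["train"]] * n_norm)
  n_test_norm <- floor(fr[["test"]] * n_norm)
  if (n_train_norm < 1 || n_test_norm < 1) {
    stop("split fractions give an empty train or test partition")
  }
  # match ACL observation counts to NORM observation counts per partition
  n_train_acl <- min(2L * n_train_norm, length(acl_subjects))
  n_test_acl <- min(2L * n_test_norm, length(acl_subjects) - n_train_acl)
  if (n_test_acl < 1) {
    stop(sprintf("insufficient subjects in ACL cohort: %d available, %d needed for train + test",
                 length(acl_subjects), 2L * (n_train_norm + n_test_norm)))
  }
  with_seed(config$seed_bench, {
    lapply(seq_len(config$n_splits), function(s) {
      norm_perm <- sample(norm_subjects)
      acl_perm <- sample(acl_subjects)
      train <- c(norm_perm[seq_len(n_train_norm)],
                 acl_perm[seq_len(n_train_acl)])
      test <- c(norm_perm[n_train_norm + seq_len(n_test_norm)],
                acl_perm[n_train_acl + seq_len(n_test_acl)])
      holdout <- setdiff(c(norm_subjects, acl_subjects), c(train, test))
      list(split_index = s, train_subjects = train, test_subjects = test,
           holdout_subjects = holdout)
    })
  })
}

as_obs_meta <- function(x) {
  if (inherits(x, "movement_dataset") || inherits(x, "feature_matrix")) {
    x <- x$meta
  }
  stopifnot(is.data.frame(x),
            all(c("subject_id", "class_label") %in% names(x)))
  x
}

#' Z-score features with training-set statistics
#'
#' Each feature (column) is centered and scaled with the mean and standard
#' deviation of the training rows; the test rows use the same statistics.
#' Features with zero training standard deviation map to 0 in both sets and
#' are reported in the `constant` attribute.
#'
#' @param train,test numeric matrices, observations in rows, the same
#'   feature columns in both.
#' @return list with normalized `train` and `test` matrices and a
#'   `constant` logical vector flagging zero-variance training features.
#' @export
zscore_fit_apply <- function(train, test) {
  stopifnot(is.matrix(train), is.matrix(test), ncol(train) == ncol(test))
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  constant <- !is.finite(sd) | sd == 0
  sd[constant] <- 1
  ztr <- sweep(sweep(train, 2, mu), 2, sd, "/")
  zte <- sweep(sweep(test, 2, mu), 2, sd, "/")
  if (any(constant)) {
    ztr[, constant] <- 0
    zte[, constant] <- 0
  }
  list(train = ztr, test = zte, constant = constant)
}

# drop training-constant columns for fits that cannot tolerate them;
# keeps column names intact
drop_constant <- function(xtr, xte) {
  sd <- apply(xtr, 2, stats::sd)
  keep <- is.finite(sd) & sd > 0
  if (!any(keep)) keep[1] <- TRUE
  list(train = xtr[, keep, drop = FALSE], test = xte[, keep, drop = FALSE])
}

#' Train one technique and predict test labels
#'
#' Standard techniques are delegated to their established implementations at
#' library defaults: multinomial logistic regression (`nnet::multinom`),
#' linear discriminant analysis (`MASS::lda`), k-nearest neighbour with
#' k = 5 (`class::knn`), Gaussian naive Bayes (`e1071::naiveBayes`), a CART
#' decision tree (`rpart::rpart`), a bagged-tree ensemble of 50 trees
#' (`randomForest::randomForest`, ntree = 50), a linear-kernel support
#' vector machine with pairwise (one-vs-one) multiclass coding
#' (`e1071::svm`), and a feed-forward neural network with one hidden layer
#' of 10 units trained with cross-entropy loss and early stopping on a 15%
#' validation carve-out of the training rows (`nnet::nnet`). Two
#' template-matching baselines are implemented directly: `correlation2mean`
#' assigns a test row to the class whose training-mean feature vector has
#' the highest Pearson correlation with it (requires at least 2 features),
#' and `distance2mean` to the class with the smallest Euclidean distance.
#'
#' @param technique_id one of [technique_panel()].
#' @param xtr training matrix (observations x features).
#' @param ytr training labels (character or factor over [limb_classes()]).
#' @param xte test matrix with the same feature columns.
#' @param seed seed for stochastic fits (bagging, network initialization,
#'   validation carve-out); deterministic techniques ignore it.
#' @return character vector of predicted class labels, one per test row.
#' @export
train_predict <- function(technique_id, xtr, ytr, xte, seed = 1L) {
  stopifnot(is.matrix(xtr), is.matrix(xte), nrow(xtr) == length(ytr))
  classes <- intersect(limb_classes(), unique(as.character(ytr)))
  y <- factor(as.character(ytr), levels = classes)
  colnames(xtr) <- colnames(xte) <- paste0("f", seq_len(ncol(xtr)))
  pred <- switch(
    technique_id,
    regression = {
      d <- drop_constant(xtr, xte)
      df <- data.frame(d$train)
      df$.y <- y
      fit <- with_seed(seed, nnet::multinom(.y ~ ., data = df, trace = FALSE,
                                            MaxNWts = 10000))
      as.character(stats::predict(fit, newdata = data.frame(d$test)))
    },
    discriminant = {
      d <- drop_constant(xtr, xte)
      fit <- MASS::lda(d$train, grouping = y)
      as.character(stats::predict(fit, d$test)$class)
    },
    knn = {
      as.character(class::knn(xtr, xte, cl = y, k = 5))
    },
    naive_bayes = {
      d <- drop_constant(xtr, xte)
      fit <- e1071::naiveBayes(d$train, y)
      as.character(stats::predict(fit, d$test))
    },
    decision_tree = {
      df <- data.frame(xtr)
      df$.y <- y
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      as.character(stats::predict(fit, newdata = data.frame(xte), type = "class"))
    },
    random_forest = {
      fit <- with_seed(seed, randomForest::randomForest(xtr, y, ntree = 50))
      as.character(stats::predict(fit, xte))
    },
    svm = {
      d <- drop_constant(xtr, xte)
      fit <- e1071::svm(d$train, y, kernel = "linear")
      as.character(stats::predict(fit, d$test))
    },
    neural_network = {
      fit_nnet_early_stop(xtr, y, xte, seed = seed)
    },
    correlation2mean = {
      if (ncol(xtr) < 2) stop("correlation2mean needs >=2 features")
      centroids <- class_centroids(xtr, y)
      score <- suppressWarnings(stats::cor(t(xte), t(centroids)))
      score[is.na(score)] <- -Inf
      classes[max.col(score, ties.method = "first")]
    },
    distance2mean = {
      centroids <- class_centroids(xtr, y)
      d2 <- outer(rowSums(xte^2), rep(1, nrow(centroids))) -
        2 * xte %*% t(centroids) +
        outer(rep(1, nrow(xte)), rowSums(centroids^2))
      classes[max.col(-d2, ties.method = "first")]
    },
    stop("unknown technique: ", technique_id)
  )
  pred
}

class_centroids <- function(x, y) {
  cent <- do.call(rbind, lapply(levels(y), function(cl) {
    colMeans(x[y == cl, , drop = FALSE])
  }))
  rownames(cent) <- levels(y)
  cent
}

# one hidden layer of 10 units, softmax output, cross-entropy loss;
# early stopping monitors cross-entropy on a stratified 15% carve-out
fit_nnet_early_stop <- function(xtr, y, xte, seed, size = 10L,
                                chunk = 50L, max_chunks = 8L, patience = 2L) {
  with_seed(seed, {
    val_idx <- unlist(lapply(levels(y), function(cl) {
      i <- which(y == cl)
      sample(i, max(1L, floor(0.15 * length(i))))
    }))
    fit_idx <- setdiff(seq_along(y), val_idx)
    ytab <- nnet::class.ind(y)
    fit <- nnet::nnet(xtr[fit_idx, , drop = FALSE], ytab[fit_idx, , drop = FALSE],
                      size = size, softmax = TRUE, maxit = chunk, trace = FALSE)
    best <- fit
    best_loss <- nnet_val_loss(fit, xtr[val_idx, , drop = FALSE],
                               ytab[val_idx, , drop = FALSE])
    bad <- 0L
    for (k in seq_len(max_chunks - 1L)) {
      fit <- nnet::nnet(xtr[fit_idx, , drop = FALSE], ytab[fit_idx, , drop = FALSE],
                        size = size, softmax = TRUE, maxit = chunk,
                        Wts = fit$wts, trace = FALSE)
      loss <- nnet_val_loss(fit, xtr[val_idx, , drop = FALSE],
                            ytab[val_idx, , drop = FALSE])
      if (loss < best_loss - 1e-8) {
        best <- fit
        best_loss <- loss
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
    p <- stats::predict(best, xte)
    levels(y)[max.col(p, ties.method = "first")]
  })
}

nnet_val_loss <- function(fit, xval, yval) {
  p <- pmax(stats::predict(fit, xval), 1e-12)
  -mean(rowSums(yval * log(p)))
}

#' Evaluate one technique across a split plan
#'
#' Per split: observation columns are sliced by subject membership, features
#' are optionally z-scored with training statistics, the technique is
#' trained and test-set labels predicted; per-split accuracy and
#' per-observation prediction records are collected. Holdout observations
#' are never touched. A technique failure on a split is logged and the
#' split skipped; more than 10% failed splits is an error.
#'
#' @param features a `feature_matrix`.
#' @param technique_id one of [technique_panel()].
#' @param plans split plans from [plan_splits()].
#' @param config an [analysis_config()].
#' @param normalization overrides `config$normalization` if given.
#' @return an object of class `technique_result` with fields
#'   `technique_id`, `normalization`, `per_split_accuracy`,
#'   `mean_accuracy` and `records` (data.frame: split, subject_id,
#'   limb_side, actual, predicted).
#' @export
evaluate_technique <- function(features, technique_id, plans, config,
                               normalization = NULL) {
  stopifnot(inherits(features, "feature_matrix"), length(plans) >= 1)
  normalization <- normalization %||% config$normalization
  meta <- features$meta
  x_all <- t(features$values)   # observations x features
  acc <- numeric(0)
  recs <- vector("list", length(plans))
  failed <- 0L
  for (p in plans) {
    tr <- meta$subject_id %in% p$train_subjects
    te <- meta$subject_id %in% p$test_subjects
    xtr <- x_all[tr, , drop = FALSE]
    xte <- x_all[te, , drop = FALSE]
    if (normalization == "zscore") {
      z <- zscore_fit_apply(xtr, xte)
      xtr <- z$train
      xte <- z$test
    }
    seed <- derive_seed(config$seed_bench, paste0(technique_id, ":", p$split_index))
    pred <- tryCatch(
      train_predict(technique_id, xtr, meta$class_label[tr], xte, seed = seed),
      error = function(e) e
    )
    if (inherits(pred, "error")) {
      failed <- failed + 1L
      warning(sprintf("technique %s failed on split %d: %s",
                      technique_id, p$split_index, conditionMessage(pred)),
              call. = FALSE)
      next
    }
    actual <- meta$class_label[te]
    acc <- c(acc, mean(pred == actual))
    recs[[p$split_index]] <- data.frame(
      split = p$split_index,
      subject_id = meta$subject_id[te],
      limb_side = meta$limb_side[te],
      actual = actual,
      predicted = pred,
      stringsAsFactors = FALSE
    )
  }
  if (failed > 0.10 * length(plans)) {
    stop(sprintf("technique %s failed on %d of %d splits", technique_id,
                 failed, length(plans)))
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  rownames(records) <- NULL
  structure(list(technique_id = technique_id,
                 normalization = normalization,
                 per_split_accuracy = acc,
                 mean_accuracy = mean(acc),
                 n_failed_splits = failed,
                 records = records),
            class = "technique_result")
}

#' @export
print.technique_result <- function(x, ...) {
  cat(sprintf("<technique_result> %s (%s): mean accuracy %.3f over %d splits\n",
              x$technique_id, x$normalization, x$mean_accuracy,
              length(x$per_split_accuracy)))
  invisible(x)
}

#' Rank the technique panel
#'
#' Evaluates every panel technique under both raw and z-scored features over
#' the same split plans and reports mean accuracies side by side. The
#' winner is the technique with the highest mean accuracy under the
#' configured normalization; ties break by panel order.
#'
#' @param features a `feature_matrix`.
#' @param plans split plans from [plan_splits()].
#' @param config an [analysis_config()].
#' @param techniques subset of [technique_panel()] to evaluate.
#' @return list with `table` (data.frame: technique, accuracy_raw,
#'   accuracy_zscore), `winner` (technique id) and `results` (the
#'   `technique_result` objects under the configured normalization).
#' @export
rank_techniques <- function(features, plans, config,
                            techniques = technique_panel()) {
  res <- list()
  tab <- data.frame(technique = techniques,
                    accuracy_raw = NA_real_,
                    accuracy_zscore = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(techniques)) {
    t_id <- techniques[i]
    for (nz in c("raw", "zscore")) {
      r <- evaluate_technique(features, t_id, plans, config, normalization = nz)
      tab[[paste0("accuracy_", nz)]][i] <- r$mean_accuracy
      if (nz == config$normalization) res[[t_id]] <- r
    }
  }
  col <- paste0("accuracy_", config$normalization)
  winner <- tab$technique[which.max(tab[[col]])]  # which.max: first max -> panel order
  list(table = tab, winner = winner, results = res)
}

#' Random-guess baseline across a split plan
#'
#' Per split, every test observation is assigned one of the three classes
#' uniformly at random; the best guess is the highest per-split guess
#' accuracy and serves as the meaningfulness threshold for any model
#' evaluated on the same plans.
#'
#' @param meta observation metadata (or a dataset / feature matrix).
#' @param plans split plans from [plan_splits()].
#' @param config an [analysis_config()]; uses the guess-stage seed.
#' @return list with `per_split_accuracy` and `best_guess`.
#' @export
guess_baseline <- function(meta, plans, config) {
  meta <- as_obs_meta(meta)
  cls <- limb_classes()
  with_seed(config$seed_guess, {
    acc <- vapply(plans, function(p) {
      te <- meta$class_label[meta$subject_id %in% p$test_subjects]
      mean(sample(cls, length(te), replace = TRUE) == te)
    }, numeric(1))
    list(per_split_accuracy = acc, best_guess = max(acc))
  })
}
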