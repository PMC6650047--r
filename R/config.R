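#' Analysis configuration
#'
#' Bundles every tunable constant of the framework. The defaults are the
#' settings of the full-scale analysis: 100 resampling splits, a 75% support
#' threshold with a minimum phase span of 5% of the movement cycle, a 0.70
#' collinearity cut during forward selection, a 20-feature cap, a 10% elbow
#' fraction, and train/test/holdout fractions of 70/25/5% of control
#' subjects.
#'
#' @param n_splits number of shuffle splits used both for phase detection and
#'   for classifier evaluation.
#' @param support_threshold fraction of splits in which a time point must be
#'   flagged for it to count towards a robust phase.
#' @param min_span_fraction minimum span of a robust phase as a fraction of
#'   the movement cycle (0.05 -> 5 samples of the 101-sample cycle).
#' @param corr_threshold absolute Pearson correlation above which candidate
#'   features are pruned once a collinear feature has been selected.
#' @param max_features cap on the number of forward-selected features.
#' @param elbow_fraction fraction of the accuracy-curve range used as the
#'   improvement threshold by [elbow_point()].
#' @param split_fractions named numeric: train/test/holdout fractions of the
#'   control (NORM) subjects; must sum to 1.
#' @param subjects_per_group number of subjects drawn from each cohort (ACL
#'   and NORM) in every phase-detection split.
#' @param normalization `"zscore"` (features standardized with training-set
#'   statistics) or `"raw"`.
#' @param kfold_folds,kfold_train_per_class,kfold_test_per_class layout of
#'   the final k-fold re-validation (per-class subject counts).
#' @param rng_seed master seed; every stochastic stage derives an isolated
#'   stream from it.
#' @param seed_phases,seed_bench,seed_guess,seed_kfold optional stage seeds;
#'   by default each is derived from `rng_seed` so that, e.g., changing only
#'   `seed_bench` leaves the detected phases untouched.
#' @return an object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(n_splits = 100L,
                            support_threshold = 0.75,
                            min_span_fraction = 0.05,
                            corr_threshold = 0.70,
                            max_features = 20L,
                            elbow_fraction = 0.10,
                            split_fractions = c(train = 0.70, test = 0.25, holdout = 0.05),
                            subjects_per_group = 50L,
                            normalization = c("zscore", "raw"),
                            kfold_folds = 10L,
                            kfold_train_per_class = 52L,
                            kfold_test_per_class = 6L,
                            rng_seed = 1L,
                            seed_phases = NULL,
                            seed_bench = NULL,
                            seed_guess = NULL,
                            seed_kfold = NULL) {
  normalization <- match.arg(normalization)
  fr <- split_fractions
  stopifnot(
    n_splits >= 1, subjects_per_group >= 1, max_features >= 1,
    all(c("train", "test", "holdout") %in% names(fr))
  )
  if (any(fr <= 0) || any(fr > 1)) {
    stop("split fractions must lie in (0, 1]")
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("train + test + holdout fractions must sum to 1")
  }
  for (p in c("support_threshold", "min_span_fraction", "elbow_fraction")) {
    v <- get(p)
    if (v <= 0 || v > 1) stop(sprintf("%s must lie in (0, 1]", p))
  }
  cfg <- list(
    n_splits = as.integer(n_splits),
    support_threshold = support_threshold,
    min_span_fraction = min_span_fraction,
    corr_threshold = corr_threshold,
    max_features = as.integer(max_features),
    elbow_fraction = elbow_fraction,
    split_fractions = fr[c("train", "test", "holdout")],
    subjects_per_group = as.integer(subjects_per_group),
    normalization = normalization,
    kfold_folds = as.integer(kfold_folds),
    kfold_train_per_class = as.integer(kfold_train_per_class),
    kfold_test_per_class = as.integer(kfold_test_per_class),
    rng_seed = as.integer(rng_seed),
    seed_phases = as.integer(seed_phases %||% derive_seed(rng_seed, "phases")),
    seed_bench = as.integer(seed_bench %||% derive_seed(rng_seed, "bench")),
    seed_guess = as.integer(seed_guess %||% derive_seed(rng_seed, "guess")),
    seed_kfold = as.integer(seed_kfold %||% derive_seed(rng_seed, "kfold"))
  )
  structure(cfg, class = "analysis_config")
}

#' Reduced-scale configuration profile
#'
#' A down-scaled profile (20 splits, 20 subjects per cohort per
#' phase-detection split, reduced k-fold layout) that exercises every stage
#' of the framework in minutes on one CPU. Statistical properties of the
#' method are unchanged; only Monte-Carlo resolution is reduced.
#'
#' @param ... overrides passed on to [analysis_config()].
#' @return an `analysis_config`.
#' @export
reduced_config <- function(...) {
  defaults <- list(
    n_splits = 20L, subjects_per_group = 20L,
    kfold_folds = 5L, kfold_train_per_class = 10L, kfold_test_per_class = 3L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(analysis_config, args)
}

#' Read / write an analysis configuration as YAML
#'
#' @param config an `analysis_config`.
#' @param path file path.
#' @return `read_config` returns an `analysis_config`;
#'   `write_config` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  obj <- unclass(config)
  obj$split_fractions <- as.list(obj$split_fractions)
  yaml::write_yaml(c(list(schema = "limbclass-config-1"), obj), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$schema, "limbclass-config-1")) {
    stop("not a limbclass config file (missing schema line)")
  }
  obj$schema <- NULL
  obj$split_fractions <- unlist(obj$split_fractions)
  do.call(analysis_config, obj)
}
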