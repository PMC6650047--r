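# Shared settings for the analysis scripts: one synthetic study emulating
# the ACL/control cohort layout, and a reduced-resolution configuration
# (20 shuffle splits, 20 subjects per cohort per phase-detection split)
# that runs the full framework in minutes on one CPU.

library(limbclass)

RESULTS_DIR <- "results"   # small summary tables, kept with the repository
SCRATCH_DIR <- "scratch"   # bulky intermediates (raw dataset, feature matrix)
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(SCRATCH_DIR, recursive = TRUE, showWarnings = FALSE)

STUDY_SEED <- 2026L

study_spec <- function() generator_spec(rng_seed = STUDY_SEED)

study_config <- function() {
  reduced_config(
    n_splits = 20, subjects_per_group = 20, max_features = 10,
    kfold_folds = 10, kfold_train_per_class = 52, kfold_test_per_class = 6,
    rng_seed = STUDY_SEED + 1L
  )
}

res_path <- function(name) file.path(RESULTS_DIR, name)
big_path <- function(name) file.path(SCRATCH_DIR, name)

# the simulated study is a pure function of its seed, so the bulky CSV is
# a cache, not a source of truth
load_study_dataset <- function() {
  cached <- big_path("synthetic_dataset.csv")
  if (file.exists(cached)) {
    load_dataset(cached)
  } else {
    generate_dataset(read_generator_spec(res_path("generator_spec.yaml")))
  }
}
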