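test_that("phase detector: zero variance gives an all-zero mask; <2 trials error", {
  trials <- matrix(rep(sin(seq(0, pi, length.out = 101)), 10), nrow = 10, byrow = TRUE)
  expect_identical(detect_variation_phases(trials), integer(101))
  expect_error(detect_variation_phases(trials[1, , drop = FALSE]), "at least 2")
})

test_that("phase detector localizes planted two-level variation", {
  set.seed(42)
  base <- cos(seq(0, 2 * pi, length.out = 101))
  trials <- matrix(rep(base, 40), nrow = 40, byrow = TRUE)
  level <- rep(c(0, 1), each = 20)
  idx <- 41:61  # cycle indices 40..60
  trials[, idx] <- trials[, idx] + outer(level, rep(1, length(idx))) +
    matrix(rnorm(40 * length(idx), 0, 0.05), 40)
  mask <- detect_variation_phases(trials)
  inside <- mask[idx]
  expect_gte(mean(inside), 0.8)                       # covers >= 80% of the window
  margin <- setdiff(seq_len(101), (41 - 5):(61 + 5))  # 5-sample margin
  expect_identical(unique(mask[margin]), 0L)
})

test_that("phase detector mask is invariant to a constant shift of all trials", {
  set.seed(7)
  trials <- matrix(rnorm(20 * 101), nrow = 20)
  expect_identical(detect_variation_phases(trials),
                   detect_variation_phases(trials + 5))
})

test_that("memory matrix bits conserve into support counts", {
  d <- generate_dataset(tiny_spec(seed = 3))
  cfg <- reduced_config(n_splits = 8, subjects_per_group = 5, rng_seed = 2)
  sup <- build_support(d, cfg)
  for (sv in sup$signals) {
    expect_true(all(sv$bits %in% 0:1))
    expect_identical(dim(sv$bits), c(101L, 8L))
    expect_identical(sv$counts, as.integer(rowSums(sv$bits)))
  }
})

test_that("an all-ones detector saturates every support count at n_splits", {
  d <- generate_dataset(tiny_spec(seed = 3))
  cfg <- reduced_config(n_splits = 6, subjects_per_group = 5, rng_seed = 2)
  sup <- build_support(d, cfg, detector = function(trials) rep(1L, 101))
  for (sv in sup$signals) expect_identical(sv$counts, rep(6L, 101))
})

test_that("build_support refuses cohorts smaller than the per-split draw", {
  d <- generate_dataset(tiny_spec(n_norm = 4, n_acl = 10, seed = 1))
  cfg <- reduced_config(n_splits = 3, subjects_per_group = 5, rng_seed = 1)
  expect_error(build_support(d, cfg), "insufficient subjects.*NORM")
})

test_that("robust-phase extraction applies support threshold and span rule", {
  cfg <- analysis_config(n_splits = 100)
  counts <- integer(101)
  counts[11:31] <- 80L  # cycle indices 10..30
  ph <- extract_robust_phases(counts, cfg, signal_name = "s")
  expect_identical(nrow(ph), 1L)
  expect_identical(ph$start_idx, 10L)
  expect_identical(ph$end_idx, 30L)
  expect_identical(ph$min_support, 80L)

  short <- integer(101)
  short[11:13] <- 80L   # span 3 < 5
  expect_identical(nrow(extract_robust_phases(short, cfg)), 0L)

  sub <- rep(74L, 101)  # strictly below the ceiling(0.75 * 100) = 75 threshold
  expect_identical(nrow(extract_robust_phases(sub, cfg)), 0L)
  at <- rep(75L, 101)
  expect_identical(nrow(extract_robust_phases(at, cfg)), 1L)
})

test_that("robust-phase extraction matches the direct-threshold oracle on random supports", {
  cfg <- reduced_config(n_splits = 20)
  threshold <- ceiling(0.75 * 20)
  set.seed(123)
  for (rep in 1:200) {
    counts <- sample(0:20, 101, replace = TRUE)
    got <- extract_robust_phases(counts, cfg, n_splits = 20)
    want <- phase_oracle(counts, threshold, min_span = 5)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$start_idx, as.integer(want[, "start"]))
      expect_identical(got$end_idx, as.integer(want[, "end"]))
    }
    # every emitted phase satisfies its own invariants
    if (nrow(got)) {
      expect_true(all(got$end_idx - got$start_idx + 1 >= 5))
      expect_true(all(got$min_support >= threshold))
    }
  }
})

test_that("phase-mean features: constants, arithmetic means and label style", {
  meta <- data.frame(subject_id = c("s1", "s1"), limb_side = c("left", "right"),
                     class_label = c("NORM", "NORM"))
  sig <- list("knee flexion angular velocity" = cbind(rep(2, 101), 0:100))
  d <- movement_dataset("EX", "single_leg", meta, sig)
  phases <- data.frame(signal = "knee flexion angular velocity",
                       start_idx = c(5L, 74L), end_idx = c(15L, 81L))
  fm <- build_feature_matrix(d, phases)
  expect_equal(unname(fm$values[1, 1]), 2)  # mean of a constant
  expect_equal(unname(fm$values[1, 2]), 10) # mean of 5..15
  expect_identical(fm$features$label[2], "knee flexion angular velocity (74 to 81%)")
  expect_error(build_feature_matrix(d, data.frame(signal = "nope", start_idx = 0L,
                                                  end_idx = 10L)),
               "unknown signal")
})

test_that("feature count equals total phase count; columns equal dataset size", {
  d <- generate_dataset(tiny_spec(seed = 8))
  cfg <- reduced_config(n_splits = 10, subjects_per_group = 6, rng_seed = 4)
  sup <- build_support(d, cfg)
  ph <- robust_phases(sup, cfg)
  fm <- build_feature_matrix(d, ph, cfg)
  expect_identical(nrow(fm$values), nrow(ph))
  expect_identical(ncol(fm$values), n_observations(d))
})

test_that("symmetry augmentation discovers symmetry signals before phase detection", {
  spec <- tiny_spec(n_norm = 6, n_acl = 10, seed = 5, mode = "double_leg")
  d <- generate_dataset(spec)
  aug <- augment_symmetry(d)
  expect_setequal(names(aug$signals),
                  c("knee_flex", "grf", "knee_flex symmetry", "grf symmetry"))
  # symmetry of a NORM limb is its waveform minus the contralateral one
  i <- which(aug$meta$subject_id == "norm_001" & aug$meta$limb_side == "left")
  j <- which(aug$meta$subject_id == "norm_001" & aug$meta$limb_side == "right")
  expect_equal(aug$signals[["grf symmetry"]][, i],
               aug$signals$grf[, i] - aug$signals$grf[, j])
  expect_equal(aug$signals[["grf symmetry"]][, j],
               -aug$signals[["grf symmetry"]][, i])
  # single-leg datasets pass through untouched
  expect_identical(augment_symmetry(generate_dataset(tiny_spec(seed = 5))),
                   generate_dataset(tiny_spec(seed = 5)))
})
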