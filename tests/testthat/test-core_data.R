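test_that("dataset construction enforces waveform and label invariants", {
  meta <- data.frame(subject_id = c("s1", "s1"), limb_side = c("left", "right"),
                     class_label = c("NORM", "NORM"))
  sig <- list(a = matrix(0, 101, 2))
  d <- movement_dataset("EX", "single_leg", meta, sig)
  expect_s3_class(d, "movement_dataset")
  expect_identical(n_observations(d), 2L)

  expect_error(movement_dataset("EX", "single_leg", meta, list(a = matrix(0, 100, 2))),
               "101")
  expect_error(movement_dataset("EX", "single_leg",
                                transform(meta, class_label = c("NORM", "CTRL")), sig),
               "unknown class")
  bad <- sig
  bad$a[5, 1] <- NA
  expect_error(movement_dataset("EX", "single_leg", meta, bad), "non-finite")
})

test_that("loader bookkeeping: small well-formed file yields one observation per limb", {
  spec <- tiny_spec(n_norm = 2, n_acl = 1, seed = 5)
  spec$signal_specs <- spec$signal_specs[1]
  d <- generate_dataset(spec)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, f)
  d2 <- load_dataset(f)
  expect_identical(n_observations(d2), 6L)  # 2 NORM subjects x 2 limbs + 1 ACL x 2
  expect_identical(sort(unique(d2$meta$class_label)), sort(c("ACL_OP", "ACL_NO_OP", "NORM")))
})

test_that("full-scale synthetic export round-trips bit-exactly", {
  spec <- generator_spec(signal_specs = default_signal_specs()[1:3], rng_seed = 11)
  d <- generate_dataset(spec)
  expect_identical(n_observations(d), 436L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, f)
  d2 <- load_dataset(f)
  expect_identical(d$meta, d2$meta)
  expect_identical(lapply(d$signals, unname), lapply(d2$signals, unname))
  expect_identical(d$exercise_id, d2$exercise_id)
})

test_that("malformed files are rejected with errors naming the culprit", {
  spec <- tiny_spec(n_norm = 2, n_acl = 1, seed = 5)
  d <- generate_dataset(spec)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, f)
  lines <- readLines(f)

  # drop one sample of one waveform -> malformed, message names obs and signal
  drop_at <- grep("^norm_001,left,NORM,SYN,knee_flex,50,", lines)[1]
  writeLines(lines[-drop_at], f)
  expect_error(load_dataset(f), "malformed waveform.*norm_001.*knee_flex")

  # unknown class string
  writeLines(sub("^norm_001,left,NORM", "norm_001,left,CTRL", lines), f)
  expect_error(load_dataset(f), "unknown class")

  # duplicated (subject, limb) with conflicting classes
  dup <- sub("^norm_001,left,NORM", "norm_002,left,NORM", lines[grep("^norm_001,left,NORM", lines)])
  writeLines(c(lines, dup), f)
  expect_error(load_dataset(f), "malformed waveform|duplicate")
})

test_that("structural validation reports pairing violations without raising", {
  d <- generate_dataset(tiny_spec(n_norm = 3, n_acl = 3, seed = 2))
  expect_identical(nrow(validate_structure(d)), 0L)

  # ACL subject with only one limb
  one_limb <- subset_observations(d, !(d$meta$subject_id == "acl_001" &
                                         d$meta$class_label == "ACL_NO_OP"))
  rep1 <- validate_structure(one_limb)
  expect_true(any(rep1$subject_id == "acl_001" &
                    grepl("ACL_NO_OP", rep1$message)))

  # NORM subject with two left limbs
  twisted <- d
  twisted$meta$limb_side[twisted$meta$subject_id == "norm_001"] <- "left"
  rep2 <- validate_structure(twisted)
  expect_true(any(rep2$subject_id == "norm_001" & rep2$rule == "duplicate_limb"))
})

test_that("feature matrices and configs round-trip through their writers", {
  d <- generate_dataset(tiny_spec(seed = 3))
  cfg <- reduced_config(n_splits = 5, subjects_per_group = 4, rng_seed = 3)
  sup <- build_support(d, cfg)
  fm <- build_feature_matrix(d, robust_phases(sup, cfg), cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, f)
  fm2 <- read_feature_matrix(f)
  expect_identical(unname(fm$values), unname(fm2$values))
  expect_identical(fm$features$label, fm2$features$label)
  expect_identical(fm$meta, fm2$meta)

  yml <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, yml)
  expect_identical(read_config(yml), cfg)

  gy <- withr::local_tempfile(fileext = ".yaml")
  write_generator_spec(tiny_spec(seed = 3), gy)
  spec2 <- read_generator_spec(gy)
  expect_identical(generate_dataset(spec2), d)
})
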