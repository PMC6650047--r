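# Shared fixtures, all generated in code.

# a small, fast generator spec: 2 signals, strong localized effects
tiny_spec <- function(n_norm = 8, n_acl = 20, seed = 1, mode = "single_leg",
                      subject_sd = 0.15, noise_sd = 0.2) {
  specs <- list(
    signal_spec("knee_flex", rep(0, 101),
                effect_window(40, 60, 1.0, 0.6),
                subject_sd = subject_sd, noise_sd = noise_sd),
    signal_spec("grf", rep(1, 101),
                subject_sd = subject_sd, noise_sd = noise_sd)
  )
  generator_spec(n_norm, n_acl, specs, exercise_mode = mode, rng_seed = seed)
}

# metadata for a study layout without generating waveforms
make_meta <- function(n_norm = 62, n_acl = 156) {
  rbind(
    data.frame(subject_id = rep(sprintf("n%03d", seq_len(n_norm)), each = 2),
               limb_side = rep(c("left", "right"), n_norm),
               class_label = "NORM", stringsAsFactors = FALSE),
    data.frame(subject_id = rep(sprintf("a%03d", seq_len(n_acl)), each = 2),
               limb_side = rep(c("left", "right"), n_acl),
               class_label = rep(c("ACL_OP", "ACL_NO_OP"), n_acl),
               stringsAsFactors = FALSE)
  )
}

# feature matrix with planted class-mean shifts: one row per entry of
# `shifts` (shift applied as ACL_OP = +s, ACL_NO_OP = +s/2, NORM = 0)
make_shifted_features <- function(meta, shifts, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  cls <- meta$class_label
  mult <- c(ACL_OP = 1, ACL_NO_OP = 0.5, NORM = 0)[cls]
  vals <- t(vapply(seq_along(shifts), function(i) {
    shifts[i] * mult + rnorm(nrow(meta), 0, noise_sd)
  }, numeric(nrow(meta))))
  rownames(vals) <- sprintf("feat%02d (0 to 100%%)", seq_along(shifts))
  feature_matrix(vals, meta = meta)
}

# independent brute-force elbow scan (oracle for elbow_point)
elbow_oracle <- function(f, frac = 0.10) {
  thr <- (max(f) - min(f)) * frac
  for (n in seq_len(length(f) - 1)) {
    if (f[n + 1] - f[n] < thr) return(n)
  }
  length(f)
}

# independent robust-phase oracle: direct thresholding scan
phase_oracle <- function(counts, threshold, min_span) {
  above <- counts >= threshold
  out <- NULL
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_span) {
        out <- rbind(out, c(start = i - 1L, end = j - 1L))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

jaccard_interval <- function(a_start, a_end, b_start, b_end) {
  inter <- max(0, min(a_end, b_end) - max(a_start, b_start) + 1)
  union <- (a_end - a_start + 1) + (b_end - b_start + 1) - inter
  inter / union
}
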