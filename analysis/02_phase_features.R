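#!/usr/bin/env Rscript
# Stage 1: feature engineering.
#
# Accumulates the per-signal memory matrix over resampled subject subsets,
# extracts robust phases of variation (>= 75% support, >= 5% of the cycle)
# and reduces every waveform to its phase means.

source("analysis/00_common.R")

dataset <- load_study_dataset()
config <- read_config(res_path("analysis_config.yaml"))

dataset <- augment_symmetry(dataset)   # no-op for single-leg exercises
support <- build_support(dataset, config)
phases <- robust_phases(support, config)

cat("Robust phases of variation:\n")
print(phases)

features <- build_feature_matrix(dataset, phases, config)
print(features)
cat(sprintf("\n%d features x %d observations (one feature per robust phase).\n",
            nrow(features$values), ncol(features$values)))

write_phases(phases, res_path("phases.json"))
write_feature_matrix(features, big_path("features.csv"))

support_tab <- do.call(rbind, lapply(support$signals, function(sv) {
  data.frame(signal = sv$signal, t = 0:100, support = sv$counts)
}))
utils::write.csv(support_tab, res_path("support_vectors.csv"), row.names = FALSE)
cat("Wrote phases.json and support_vectors.csv (results/), features.csv (scratch/).\n")
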