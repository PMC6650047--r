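#!/usr/bin/env Rscript
# Stage 0: simulate the study cohort.
#
# Generates the synthetic movement dataset that stands in for the
# (undeposited) motion-capture data: 62 control subjects contributing both
# limbs and 156 ACL-reconstructed subjects contributing one operated and one
# contralateral limb each, 8 signals, localized class effects in 4 of them.

source("analysis/00_common.R")

spec <- study_spec()
dataset <- generate_dataset(spec)

stopifnot(nrow(validate_structure(dataset)) == 0)
print(dataset)
cat("\nPlanted ground truth (effect windows):\n")
print(planted_truth(spec))

write_dataset(dataset, big_path("synthetic_dataset.csv"))
write_generator_spec(spec, res_path("generator_spec.yaml"))
write_config(study_config(), res_path("analysis_config.yaml"))
cat("\nWrote", big_path("synthetic_dataset.csv"),
    "(bulky cache) and the spec/config YAMLs under results/.\n")
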