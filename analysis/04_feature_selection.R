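#!/usr/bin/env Rscript
# Stage 3: forward wrapper feature selection and the minimal feature model.
#
# Greedily grows a model with the winning technique, pruning candidates
# that correlate |r| > 0.70 with anything already selected, then cuts the
# accuracy curve at the elbow to obtain the minimal feature model.

source("analysis/00_common.R")

features <- read_feature_matrix(big_path("features.csv"))
config <- read_config(res_path("analysis_config.yaml"))
winner <- jsonlite::read_json(res_path("bench_summary.json"))$winner

plans <- plan_splits(features, config)
trace <- forward_select(features, winner, plans, config)
print(trace)

minimal <- minimal_model(trace)
cat(sprintf("\nMinimal feature model (%d of %d selected features):\n",
            length(minimal), length(trace$selected)))
for (lab in minimal) cat("  -", lab, "\n")

write_selection_trace(trace, res_path("selection_trace.json"))
cat("Wrote selection_trace.json.\n")
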