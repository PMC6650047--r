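#!/usr/bin/env Rscript
# Stage 2: selection of the supervised learning technique.
#
# Evaluates the 10-technique panel under raw and z-scored features across
# subject-level stratified shuffle splits, records the random-guess
# baseline, and picks the technique with the highest mean accuracy.

source("analysis/00_common.R")

features <- read_feature_matrix(big_path("features.csv"))
config <- read_config(res_path("analysis_config.yaml"))

plans <- plan_splits(features, config)
ranking <- rank_techniques(features, plans, config)
guess <- guess_baseline(features, plans, config)

cat("Technique panel, mean accuracy over", config$n_splits, "splits:\n")
print(transform(ranking$table,
                accuracy_raw = round(100 * accuracy_raw, 1),
                accuracy_zscore = round(100 * accuracy_zscore, 1)))
cat(sprintf("\nWinner (%s normalization): %s\n", config$normalization, ranking$winner))
cat(sprintf("Best guess over the splits: %.1f%% (mean guess %.1f%%)\n",
            100 * guess$best_guess, 100 * mean(guess$per_split_accuracy)))

utils::write.csv(ranking$table, res_path("technique_ranking.csv"), row.names = FALSE)
win <- ranking$results[[ranking$winner]]
utils::write.csv(win$records, big_path("winner_records.csv"), row.names = FALSE)
jsonlite::write_json(list(winner = ranking$winner,
                          best_guess = guess$best_guess,
                          guess_per_split = guess$per_split_accuracy),
                     res_path("bench_summary.json"), auto_unbox = TRUE, digits = NA)
cat("Wrote technique_ranking.csv and bench_summary.json (results/), winner_records.csv (scratch/).\n")
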