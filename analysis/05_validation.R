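#!/usr/bin/env Rscript
# Stage 4: evaluation of the minimal feature model.
#
# Re-evaluates the minimal model across the shuffle splits, accumulates the
# limb-level confusion matrix, collapses it to the ACL/NORM group level,
# computes per-class sensitivities and subject-level consistency, judges
# meaningfulness against the best guess, and re-validates with the
# subject-subsampled k-fold design (52 training / 6 test subjects per class,
# accuracy resolution 1/18).

source("analysis/00_common.R")

features <- read_feature_matrix(big_path("features.csv"))
config <- read_config(res_path("analysis_config.yaml"))
bench <- jsonlite::read_json(res_path("bench_summary.json"))
trace <- read_selection_trace(res_path("selection_trace.json"))

minimal <- minimal_model(trace)
fm_min <- subset_features(features, minimal)
plans <- plan_splits(features, config)

res <- evaluate_technique(fm_min, trace$technique_id, plans, config)
cm <- accumulate_confusion(res$records)
group <- collapse_to_group(cm)
sens <- class_sensitivity(cm)
consist <- subject_consistency(res$records)

cat(sprintf("Minimal model (%s, %d features): mean accuracy %.1f%%\n",
            trace$technique_id, length(minimal), 100 * res$mean_accuracy))
cat(sprintf("Meaningful (min split accuracy %.1f%% > best guess %.1f%%): %s\n",
            100 * min(res$per_split_accuracy), 100 * bench$best_guess,
            meaningfulness(res, bench$best_guess)))
cat("\nConfusion matrix (rows = predicted, columns = actual):\n")
print(cm)
cat("\nPer-class sensitivity (%):\n")
print(percent(sens))
cat(sprintf("\nBinary ACL/NORM collapse: %.1f%% (multiclass %.1f%%)\n",
            100 * group$accuracy, 100 * confusion_accuracy(cm)))
cat("Never-misclassified ('true') members per class (%):\n")
print(percent(consist$true_fraction))

kv <- kfold_validate(fm_min, trace$technique_id, config)
cat(sprintf("\nK-fold re-validation: %.1f +/- %.1f%% (lowest fold %.1f%%, resolution %.2f%%)\n",
            100 * kv$mean, 100 * kv$sd, 100 * kv$lowest,
            100 / (3 * config$kfold_test_per_class)))

utils::write.csv(as.data.frame(as.table(cm)), res_path("confusion_minimal.csv"),
                 row.names = FALSE)
utils::write.csv(consist$per_subject, res_path("subject_consistency.csv"),
                 row.names = FALSE)
jsonlite::write_json(
  list(technique = trace$technique_id, minimal = minimal,
       mean_accuracy = res$mean_accuracy,
       per_split_accuracy = res$per_split_accuracy,
       meaningful = meaningfulness(res, bench$best_guess),
       sensitivity = as.list(sens), binary_accuracy = group$accuracy,
       true_fraction = as.list(consist$true_fraction),
       kfold = kv[c("per_fold_accuracy", "mean", "sd", "lowest")]),
  res_path("validation_summary.json"), auto_unbox = TRUE, digits = NA)
cat("Wrote confusion_minimal.csv, subject_consistency.csv and validation_summary.json.\n")
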