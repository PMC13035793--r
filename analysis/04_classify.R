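#!/usr/bin/env Rscript
# Stage 4: classification.
#
# Class-weighted classification of group membership from the 15 regional
# activity indices (global excluded as redundant, variability SDs not in
# the feature set): nested cross-validated permutation feature
# importance, iterative elimination to a reduced feature set, then a
# separate stratified 5-fold evaluation with pooled predictions, Wilson
# intervals (whole-sample n convention) and Hanley-McNeil AUC intervals.

library(povmotion)

feats <- as.data.frame(data.table::fread("results/features_w5.csv"))
feats$group <- factor(feats$group, levels = c("case", "control"))
X <- as.matrix(feats[, region_names()])
rownames(X) <- feats$subject_id
y <- feats$group
proto <- cv_protocol()  # 5 outer / 3 inner / 5 eval folds, seed 42

cat("nested permutation feature importance (6 model families)...\n")
imp <- permutation_importance_nested(X, y, proto)
data.table::fwrite(
  data.frame(feature = names(imp$importance), importance = imp$importance,
             imp$per_model),
  "results/feature_importance.csv")
print(round(sort(imp$importance, decreasing = TRUE), 4))

cat("\niterative feature elimination...\n")
selected <- eliminate_features(imp$importance, X, y, proto)
cat("selected features:", paste(selected, collapse = ", "), "\n")
writeLines(selected, "results/selected_features.txt")

cat("\nfinal 5-fold evaluation on the selected set...\n")
Xs <- X[, selected, drop = FALSE]
params <- tune_models(Xs, y, proto)
report <- evaluate_models(Xs, y, proto, params = params)
tab <- report_table(report)
data.table::fwrite(tab, "results/classification_metrics.csv")
roc <- do.call(rbind, lapply(report, function(r) cbind(model = r$model, r$roc)))
data.table::fwrite(roc, "results/roc_points.csv")
jsonlite::write_json(
  lapply(report, function(r) r[setdiff(names(r), c("roc", "scores", "predictions"))]),
  "results/classification_report.json", auto_unbox = TRUE, digits = NA)

best <- tab$model[which.max(tab$auc)]
cat(sprintf("\nbest model: %s | accuracy %.2f%% (%.1f-%.1f) | AUC %.2f (%.2f-%.2f)\n",
            best, tab$accuracy[tab$model == best],
            tab$accuracy_lo[tab$model == best], tab$accuracy_hi[tab$model == best],
            tab$auc[tab$model == best],
            tab$auc_lo[tab$model == best], tab$auc_hi[tab$model == best]))
print(tab[, c("model", "TP", "FP", "TN", "FN", "accuracy", "sensitivity",
              "specificity", "f1", "auc")], digits = 3)
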