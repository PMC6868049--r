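#!/usr/bin/env Rscript
# Stage 5: classification and evaluation.
#
# For each model layout, sweeps the top-k ranked features through an RBF-SVM
# under leave-one-out cross-validation, picks the best k, and writes the
# per-k table, the ROC / precision-recall / decision curves and the summary.

suppressPackageStartupMessages(library(rfradiomics))

out <- "results"
tables <- readRDS(file.path(out, "feature_tables.rds"))
selections <- readRDS(file.path(out, "selections.rds"))
k_max <- 15L

summary_rows <- list()
for (mdl in names(tables)) {
  tab <- tables[[mdl]]
  sel <- selections[[mdl]]
  ev <- sweep_k(tab$X[, sel$ranking, drop = FALSE], tab$y, k_max = k_max,
                model_name = mdl)
  write.csv(ev$per_k, file.path(out, sprintf("per_k_%s.csv", mdl)),
            row.names = FALSE)
  write.csv(ev$curves$roc, file.path(out, sprintf("roc_%s.csv", mdl)),
            row.names = FALSE)
  write.csv(ev$curves$prc, file.path(out, sprintf("prc_%s.csv", mdl)),
            row.names = FALSE)
  write.csv(ev$curves$dca, file.path(out, sprintf("dca_%s.csv", mdl)),
            row.names = FALSE)
  summary_rows[[mdl]] <- data.frame(
    model = mdl, n_features = ncol(tab$X), n_survivors = length(sel$survivors),
    best_k = ev$best_k, auc = ev$best$auc, accuracy = ev$best$accuracy,
    sensitivity = ev$best$sensitivity, specificity = ev$best$specificity)
}
smry <- do.call(rbind, summary_rows)
write.csv(smry, file.path(out, "model_summary.csv"), row.names = FALSE)
print(smry, row.names = FALSE)
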