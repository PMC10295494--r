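#!/usr/bin/env Rscript
# Stage 5: ROC prediction of dichotomised aortic status from EAT measures.
#
# Twelve predictor/outcome pairs: each EAT measure against stiffness index
# at or above its median, strain below its median, and distensibility
# below its median. Operating points maximise accuracy; per-pair curve
# coordinates are written as TSV files for plotting.

suppressPackageStartupMessages(library(eataorta))

derived <- utils::read.csv("results/derived_indices.csv")
grid <- roc_report(derived, criterion = "max_accuracy")

render <- function(tab) {
  tab[c("auc", "sensitivity", "specificity", "accuracy")] <-
    lapply(tab[c("auc", "sensitivity", "specificity", "accuracy")], round, 3)
  tab$threshold <- signif(tab$threshold, 4)
  tab$outcome_median <- signif(tab$outcome_median, 4)
  tab
}
utils::write.csv(render(grid), "results/table_roc.csv", row.names = FALSE)
for (key in names(attr(grid, "results"))) {
  utils::write.table(attr(grid, "results")[[key]]$curve,
                     file.path("results",
                               paste0("roc_", gsub("~", "_vs_", key), ".tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
}

cat("ROC grid (operating points maximise accuracy):\n")
print(render(grid)[c("predictor", "outcome", "auc", "threshold",
                     "sensitivity", "specificity", "accuracy")])
best <- grid[which.max(grid$accuracy), ]
cat("\nbest predictor by accuracy:", best$predictor, "for", best$outcome,
    sprintf("(accuracy %.3f, AUC %.3f)\n", best$accuracy, best$auc))
by_pred <- tapply(grid$auc, grid$predictor, mean)
cat("mean AUC by predictor:\n")
print(round(by_pred[order(-by_pred)], 3))
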