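#!/usr/bin/env Rscript
# Predictive performance on the bundled published reference results:
# OECD TG 439 metrics at each evaluation time with its cut-off, ROC/AUC,
# the accuracy-optimal cut-off interval at 42 h, and within-laboratory
# reproducibility at cut-off 7.5.

library(rheis)

dir.create("results", showWarnings = FALSE)
means <- reference_capacitance_means()
runs <- reference_capacitance_runs()

mean_scores <- function(t) {
  m <- means[means$time_h == t & means$role == "test", ]
  data.frame(chemical_casrn = m$chemical_casrn, score = m$mean,
             truth = m$ghs_label)
}

cutoffs <- data.frame(time_h = c(2, 24, 42), cutoff = c(1.5, 4, 7.5))
perf <- do.call(rbind, lapply(seq_len(nrow(cutoffs)), function(i) {
  sc <- mean_scores(cutoffs$time_h[i])
  r <- confusion_metrics(sc, cutoffs$cutoff[i])
  data.frame(time_h = cutoffs$time_h[i], cutoff = cutoffs$cutoff[i],
             sensitivity = r$sensitivity, specificity = r$specificity,
             accuracy = r$accuracy, auc = auc(sc),
             oecd_compliant = r$oecd_compliant)
}))
utils::write.csv(perf, "results/reference_performance.csv",
                 row.names = FALSE)
print(perf, row.names = FALSE)

opt <- optimal_cutoff(mean_scores(42))
cat(sprintf("Accuracy-optimal cut-off interval at 42 h: (%.2f, %.2f], %.0f%% accuracy\n",
            opt$lo, opt$hi, opt$accuracy))

utils::write.csv(roc_curve(mean_scores(42)), "results/roc_42h.csv",
                 row.names = FALSE)

test_runs <- runs[runs$role == "test", ]
calls <- data.frame(chemical_casrn = test_runs$chemical_casrn,
                    run = test_runs$run,
                    call = classify_capacitance(test_runs$mean, 7.5))
w <- within_lab_reproducibility(calls)
cat(sprintf("Within-laboratory reproducibility: %.0f%% (%d/%d); discordant: %s\n",
            w$percent, w$concordant, w$total,
            paste(w$discordant, collapse = ", ")))
utils::write.csv(calls, "results/run_calls_42h.csv", row.names = FALSE)
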