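#!/usr/bin/env Rscript
# Stage 7: full evaluation on the held-out test cohort: DeLong AUCs and
# pairwise tests, decile calibration with SSR, decision curves, anchored
# cutoffs, confusion matrices, subgroup and SRL analyses.
# Writes results/eval/ (JSON report, CSV tables, PDF figures).

source("analysis/00_config.R")

clinical <- read.csv(file.path(COHORT_DIR, "clinical.csv"))
risks <- read.csv(file.path(MODELS_DIR, "risks.csv"))
stopifnot(identical(risks$case_id, clinical$case_id))
te <- risks$cohort == "test"
y <- clinical$label[te]

report <- stratified_report(risks$combined[te], y, clinical[te, ])
report$pairwise <- list(
  combined_vs_clinical = delong_test(risks$combined[te], risks$clinical[te], y),
  combined_vs_ct = delong_test(risks$combined[te], risks$ct_report[te], y),
  ensemble_vs_lasso = delong_test(risks$radiomics_ith[te], risks$lasso[te], y))
report$model_aucs <- vapply(setdiff(names(risks), c("case_id", "cohort")),
                            function(m) roc_auc(risks[[m]][te], y), 0)
write_eval_report(report, file.path(EVAL_DIR, "eval_report.json"))
write.csv(report$subgroups, file.path(EVAL_DIR, "subgroup_aucs.csv"),
          row.names = FALSE)
write.csv(report$decision_curve, file.path(EVAL_DIR, "decision_curve.csv"),
          row.names = FALSE)
write.csv(report$overall$calibration$table,
          file.path(EVAL_DIR, "calibration.csv"), row.names = FALSE)
write.csv(as.data.frame(report$overall$confusion),
          file.path(EVAL_DIR, "confusion_combined.csv"))

pdf(file.path(EVAL_DIR, "figures.pdf"), width = 9, height = 3.2)
par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
# ROC curves
plot(0:1, 0:1, type = "l", lty = 3, col = "gray",
     xlab = "1 - specificity", ylab = "sensitivity", main = "ROC (test)")
cols <- c(combined = "firebrick", radiomics_ith = "steelblue",
          clinical = "darkgreen", ct_report = "orange")
for (m in names(cols)) {
  r <- risks[[m]][te]
  th <- sort(unique(r), decreasing = TRUE)
  sens <- vapply(th, function(t) mean(r[y == 1] >= t), 0)
  fpr <- vapply(th, function(t) mean(r[y == 0] >= t), 0)
  lines(c(0, fpr, 1), c(0, sens, 1), col = cols[m], lwd = 2)
}
legend("bottomright", names(cols), col = cols, lwd = 2, cex = 0.7)
# calibration
ct <- report$overall$calibration$table
plot(ct$mean_predicted, ct$observed, xlim = 0:1, ylim = 0:1, pch = 19,
     xlab = "mean predicted risk", ylab = "observed proportion",
     main = sprintf("Calibration (SSR = %.3f)",
                    report$overall$calibration$ssr))
abline(0, 1, lty = 3)
# decision curve
dcv <- report$decision_curve
plot(dcv$threshold, dcv$net_benefit, type = "l", lwd = 2, col = "firebrick",
     ylim = c(-0.05, max(dcv$treat_all, dcv$net_benefit)),
     xlab = "threshold probability", ylab = "net benefit",
     main = "Decision curve")
lines(dcv$threshold, dcv$treat_all, lty = 2)
abline(h = 0, lty = 3)
legend("topright", c("combined", "treat all", "treat none"),
       lty = c(1, 2, 3), col = c("firebrick", "black", "black"), cex = 0.7)
dev.off()

ci <- report$overall$ci
cat(sprintf("combined model: test AUC %.3f (95%% CI %.3f-%.3f), SSR %.3f\n",
            report$overall$auc, ci[1], ci[2],
            report$overall$calibration$ssr))
cat(sprintf("combined vs clinical: P = %.4g; combined vs CT: P = %.4g\n",
            report$pairwise$combined_vs_clinical$p,
            report$pairwise$combined_vs_ct$p))
cat("anchored cutoffs on the combined risk:\n")
print(unlist(report$overall$cutoffs))
if (!is.null(report$srl$auc))
  cat(sprintf("SRL subset: AUC %.3f (n = %d)\n", report$srl$auc,
              sum(clinical$lesion_size_cm[te] <= 4)))
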