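#!/usr/bin/env Rscript
# Step 4: inter-observer reliability on the six-observer comparison trials:
# percent identical observations per observer pair, agreement stratified by
# the number of behaviors present, and the 13 x 13 observer-pair confusion
# matrix.

suppressPackageStartupMessages(library(ethofear))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

cmp <- simulate_comparison_trials(seed = seed)
rel <- reliability_report(cmp)
write.csv(rel$pairwise, "results/reliability_pairwise.csv", row.names = FALSE)
cat(sprintf("mean inter-rater reliability: %.2f%% identical observations\n",
            rel$mean_percent))

by_n <- agreement_by_behavior_count(cmp)
write.csv(by_n, "results/reliability_by_n_behaviors.csv", row.names = FALSE)
cat("agreement by number of behaviors present:\n")
print(by_n, digits = 4)

cm <- confusion_matrix(cmp)
write.csv(cm$counts, "results/confusion_counts.csv")
write.csv(cm$row_percent, "results/confusion_row_percent.csv")
diag_pct <- 100 * sum(diag(cm$counts)) / sum(cm$counts)
offdiag <- cm$counts; diag(offdiag) <- 0L
bg_share <- 100 * (sum(offdiag[, "background"]) + sum(offdiag["background", ])) /
  max(sum(offdiag), 1)
cat(sprintf("confusion: %.1f%% of %d judgments on the diagonal; %.1f%% of disagreements involve background\n",
            diag_pct, sum(cm$counts), bg_share))
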