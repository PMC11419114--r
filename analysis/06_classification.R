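#!/usr/bin/env Rscript
# Step 6: linear discriminant classification of fear-learning status.
# Pseudo-inverse LDA under repeated stratified 10-fold cross-validation
# (100 models per analysis) on the 64 x 1044 session feature table:
# intact vs session-shuffled vs temporal-shuffled data, baseline/cue/post
# period subsets, and behavior-category subsets, each tested against
# chance (50%).

suppressPackageStartupMessages(library(ethofear))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

exp <- simulate_experiment(sim_config(seed = seed))
ft <- feature_table(exp$trials)
res <- run_full_analysis(ft, seed = seed, reps = 100)

write.csv(res$summary, "results/classification_summary.csv",
          row.names = FALSE)
long <- do.call(rbind, lapply(names(res$results), function(k) {
  cv <- res$results[[k]]
  data.frame(cell = k, repetition = seq_along(cv$accuracies),
             accuracy = cv$accuracies)
}))
write.csv(long, "results/classification_accuracies.csv", row.names = FALSE)

cat("classification grid (mean accuracy % +/- SEM, p vs chance):\n")
s <- res$summary
s$label <- sprintf("%-18s %-8s %-10s", s$condition, s$period, s$categories)
for (i in seq_len(nrow(s))) {
  cat(sprintf("%s %5.1f%% +/- %.2f  (n_feat %4d, p = %.3g)\n", s$label[i],
              100 * s$mean_accuracy[i], 100 * s$sem[i], s$n_features[i],
              s$p_vs_chance[i]))
}
cat("wrote results/classification_summary.csv and results/classification_accuracies.csv\n")
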