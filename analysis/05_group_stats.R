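#!/usr/bin/env Rscript
# Step 5: the univariate statistical battery. For each of the 12 behaviors,
# per-1-s-window independent-samples t-tests between paired and unpaired
# rats (the colored significance bars over the ethogram line plots),
# evaluated per session type, with the Bonferroni-corrected threshold for
# the 12-behavior family.

suppressPackageStartupMessages(library(ethofear))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

exp <- simulate_experiment(sim_config(seed = seed))
alpha <- 0.05
thr <- bonferroni(alpha, 12)
cat(sprintf("window t-tests at alpha = %.2f; Bonferroni threshold for 12 behaviors: %.6f\n",
            alpha, thr))

all_res <- list()
for (st in c("conditioning", "extinction")) {
  sel <- Filter(function(tr) tr$session_type == st, exp$trials)
  for (b in scored_behaviors()) {
    res <- suppressWarnings(window_ttests(sel, b, alpha = alpha))
    res$session_type <- st
    all_res[[paste(st, b)]] <- res
    sig <- res[res$direction != "none", ]
    if (nrow(sig) > 0) {
      cat(sprintf("%-12s %-11s: %2d/%d significant windows (%s)\n", st, b,
                  nrow(sig), nrow(res),
                  paste(unique(sig$direction), collapse = ", ")))
    }
  }
}
out <- do.call(rbind, all_res)
rownames(out) <- NULL
write.csv(out, "results/window_ttests.csv", row.names = FALSE)
cat("wrote results/window_ttests.csv\n")
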