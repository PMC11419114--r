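#!/usr/bin/env Rscript
# Step 3: comprehensive temporal ethograms. Percent behavior per 200-ms bin
# for each group x session type, the 64 x 1044 session feature table for
# classification, and quick-look stacked ethogram plots.

suppressPackageStartupMessages(library(ethofear))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

exp <- simulate_experiment(sim_config(seed = seed))

for (st in c("conditioning", "extinction")) {
  for (g in c("paired", "unpaired")) {
    ge <- group_ethogram(exp$trials, group = g, session_type = st)
    write.csv(ge, sprintf("results/ethogram_%s_%s.csv", st, g))
    png(sprintf("results/figures/ethogram_%s_%s.png", st, g),
        width = 900, height = 500)
    plot_ethogram(ge, main = sprintf("%s, %s", g, st))
    dev.off()
    cue <- period_frames("cue")
    cat(sprintf("%-12s %-9s cue-period means: freeze %.1f%%, locomote %.1f%%, light_rear %.1f%%, cup %.1f%%\n",
                st, g, mean(ge["freeze", cue]), mean(ge["locomote", cue]),
                mean(ge["light_rear", cue]), mean(ge["cup", cue])))
  }
}

ft <- feature_table(exp$trials)
write.csv(ft, "results/feature_table.csv", row.names = FALSE)
cat(sprintf("feature table: %d sessions x %d features\n",
            nrow(ft), ncol(ft) - 6))
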