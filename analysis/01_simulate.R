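#!/usr/bin/env Rscript
# Step 1: generate the synthetic experiment that stands in for the study's
# hand-scored video data: 32 rats (16 paired / 16 unpaired, sex-balanced,
# 0.5 / 0.35 mA), 2 scored sessions x 4 trials x 87 frames at 5 frames/s,
# plus nose-poke event logs and 8 six-observer comparison trials.
# Writes the canonical CSV dialects under results/data/.

suppressPackageStartupMessages(library(ethofear))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

out <- "results/data"
dir.create(file.path(out, "events"), recursive = TRUE, showWarnings = FALSE)

exp <- simulate_experiment(sim_config(seed = seed))
write_frame_labels(exp$trials, file.path(out, "frame_labels.csv"))
write_rat_metadata(exp$metadata, file.path(out, "rat_metadata.csv"))
for (log in exp$events) {
  write_event_log(log, file.path(out, "events", sprintf(
    "%s_%s.csv", attr(log, "rat_id"), attr(log, "session_id"))))
}
cmp <- simulate_comparison_trials(seed = seed)
write_frame_labels(cmp, file.path(out, "comparison_labels.csv"))

n_frames <- length(exp$trials) * frames_per_trial()
cat(sprintf("simulated %d trials (%d frames) for %d rats, %d event logs\n",
            length(exp$trials), n_frames, nrow(exp$metadata),
            length(exp$events)))
cat(sprintf("comparison set: %d trials x %d observers (%d frames/observer)\n",
            8, 6, 8 * frames_per_trial()))
cat("wrote", out, "\n")
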