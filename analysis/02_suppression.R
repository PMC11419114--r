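#!/usr/bin/env Rscript
# Step 2: conditioned suppression. Per-trial suppression ratios from each
# session's event log, session means, and the split-plot ANOVA
# [within: session; between: group, sex, intensity] plus group t-tests by
# intensity, mirroring the study's suppression analysis.

suppressPackageStartupMessages(library(ethofear))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

exp <- simulate_experiment(sim_config(seed = seed))
tab <- suppression_table(exp$events)
write.csv(tab, "results/suppression_trials.csv", row.names = FALSE)

per_session <- aggregate(ratio ~ rat_id + session_id + session_type, tab,
                         mean, na.action = na.omit)
per_session <- merge(per_session, exp$metadata, by = "rat_id")
write.csv(per_session, "results/suppression_sessions.csv", row.names = FALSE)

cat("group means of session suppression ratios:\n")
print(aggregate(ratio ~ group + session_type, per_session, mean))

anova_tab <- split_plot_anova(per_session, response = "ratio",
                              subject = "rat_id", within = "session_type",
                              between = c("group", "sex", "intensity_mA"))
write.csv(anova_tab, "results/suppression_anova.csv", row.names = FALSE)
cat("\nsplit-plot ANOVA (within: session; between: group, sex, intensity):\n")
print(anova_tab, digits = 4)

for (i in unique(per_session$intensity_mA)) {
  d <- per_session[per_session$intensity_mA == i &
                     per_session$session_type == "conditioning", ]
  tt <- two_sample_t(d$ratio[d$group == "paired"],
                     d$ratio[d$group == "unpaired"])
  cat(sprintf("\n%.2f mA conditioning, paired vs unpaired: t = %.2f, p = %.3g\n",
              i, tt$t, tt$p))
}
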