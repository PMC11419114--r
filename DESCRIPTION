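Package: ethofear
Title: Ethogram-Based Analysis of Conditioned Suppression and Fear Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing frame-level behavioral ethograms from
    Pavlovian fear-conditioning experiments in rats. Computes conditioned
    suppression ratios from operant event logs, builds per-trial and
    per-session behavior ethograms from 200-ms frame labels, quantifies
    inter-observer scoring reliability (percent identical observations and
    observer-pair confusion matrices), runs the univariate statistical
    battery (windowed two-sample t-tests, balanced split-plot ANOVA with
    Bonferroni correction), and classifies fear-learning status (paired
    vs. unpaired) with pseudo-inverse linear discriminant analysis under
    repeated stratified 10-fold cross-validation, including session-shuffle
    and temporal-shuffle null controls and period/behavior-category feature
    subsets. A semi-Markov behavior simulator and Poisson nose-poke
    generator reproduce the study design (32 rats, 4 trials/session, 87
    frames/trial at 5 frames/s) so the whole pipeline is testable without
    the original hand-scored video frames.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
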