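test_that("pooled t-test matches the explicit formula and handles degeneracy", {
  set.seed(31)
  x <- rnorm(6, 1); y <- rnorm(6)
  got <- two_sample_t(x, y)
  want <- oracle_pooled_t(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$df, 10)

  # affine invariance: t unchanged under common rescaling of both groups
  got2 <- two_sample_t(3 * x + 7, 3 * y + 7)
  expect_equal(got2$t, got$t, tolerance = 1e-10)

  # zero variance in both groups
  expect_equal(two_sample_t(rep(2, 4), rep(2, 4)), list(t = 0, df = 6, p = 1))
  expect_warning(z <- two_sample_t(rep(2, 4), rep(3, 4)), "zero")
  expect_equal(z$p, 0)
  expect_error(two_sample_t(1, 1:3), "at least 2")
})

test_that("one-sample t matches the reference and its conventions", {
  set.seed(32)
  v <- rnorm(20, 0.6, 0.1)
  got <- one_sample_t(v, 0.5)
  ref <- t.test(v, mu = 0.5)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # symmetric about mu -> t = 0, p = 1
  expect_equal(one_sample_t(c(0.4, 0.6), 0.5)$t, 0)
  expect_equal(one_sample_t(c(0.4, 0.6), 0.5)$p, 1)
  expect_equal(one_sample_t(rep(0.5, 5), 0.5), list(t = 0, df = 4, p = 1))
  expect_warning(z <- one_sample_t(rep(0.7, 5), 0.5), "zero variance")
  expect_equal(z$p, 0)

  # a degenerate null classifier (identical feature rows) never rejects:
  # all repetition accuracies are exactly 0.5, so p = 1 for every seed
  X <- matrix(1, 20, 8)
  y <- rep(c("paired", "unpaired"), each = 10)
  for (seed in 1:5) {
    cv <- repeated_cv(X, session_shuffle(y, seed = seed), k = 5, reps = 20,
                      seed = seed)
    expect_equal(one_sample_t(cv$accuracies, 0.5)$p, 1)
  }
})

test_that("windowed t-tests compare per-rat percentages between groups", {
  # paired rats ~100% freeze, unpaired 0%, one discordant paired rat
  freeze_all <- rep("freeze", 87)
  bg_all <- rep("background", 87)
  mixed <- c(rep("freeze", 86), "background")
  trials <- c(
    unlist(lapply(1:3, function(i) make_session(
      rep(list(freeze_all), 4), rat = paste0("p", i), group = "paired")),
      recursive = FALSE),
    make_session(rep(list(mixed), 4), rat = "p4", group = "paired"),
    unlist(lapply(1:4, function(i) make_session(
      rep(list(bg_all), 4), rat = paste0("u", i), group = "unpaired")),
      recursive = FALSE)
  )
  res <- suppressWarnings(window_ttests(trials, "freeze"))
  expect_equal(nrow(res), nrow(window_layout()))
  expect_true(all(res$p < 0.05))
  expect_true(all(res$direction == "paired_greater"))
  # trailing 2-frame window is flagged
  expect_identical(res$partial, c(rep(FALSE, 17), TRUE))

  # identical constant data in both groups -> t = 0, p = 1, none
  same <- c(
    unlist(lapply(1:2, function(i) make_session(
      rep(list(freeze_all), 4), rat = paste0("p", i), group = "paired")),
      recursive = FALSE),
    unlist(lapply(1:2, function(i) make_session(
      rep(list(freeze_all), 4), rat = paste0("u", i), group = "unpaired")),
      recursive = FALSE)
  )
  res0 <- window_ttests(same, "freeze")
  expect_true(all(res0$t == 0))
  expect_true(all(res0$p == 1))
  expect_true(all(res0$direction == "none"))
  expect_error(window_ttests(same[1:8], "freeze"), "2 rats per group")
})

test_that("split-plot ANOVA matches a hand sums-of-squares oracle", {
  set.seed(7)
  d <- expand.grid(subj = sprintf("s%d", 1:8), sess = sprintf("w%d", 1:4),
                   stringsAsFactors = FALSE)
  d$grp <- ifelse(d$subj %in% sprintf("s%d", 1:4), "paired", "unpaired")
  d$y <- rnorm(32) + ifelse(d$grp == "paired", 0.8, 0) +
    0.3 * as.integer(factor(d$sess))
  got <- split_plot_anova(d, "y", "subj", "sess", "grp")

  # independent oracle: classical balanced split-plot decomposition
  grand <- mean(d$y)
  ms <- tapply(d$y, d$subj, mean); mg <- tapply(d$y, d$grp, mean)
  mw <- tapply(d$y, d$sess, mean)
  mgw <- tapply(d$y, list(d$grp, d$sess), mean)
  W <- 4; S <- 8; G <- 2; npg <- 4
  ss_total <- sum((d$y - grand)^2)
  ss_subj <- W * sum((ms - grand)^2)
  ss_grp <- W * npg * sum((mg - grand)^2)
  ss_swg <- ss_subj - ss_grp
  ss_w <- S * sum((mw - grand)^2)
  gw_dev <- sweep(sweep(mgw, 1, mg), 2, mw) + grand
  ss_gw <- npg * sum(gw_dev^2)
  ss_resid <- ss_total - ss_subj - ss_w - ss_gw
  F_grp <- (ss_grp / (G - 1)) / (ss_swg / (S - G))
  F_w <- (ss_w / (W - 1)) / (ss_resid / ((S - G) * (W - 1)))
  F_gw <- (ss_gw / ((G - 1) * (W - 1))) / (ss_resid / ((S - G) * (W - 1)))

  expect_equal(got$F[got$effect == "grp"], F_grp, tolerance = 1e-8)
  expect_equal(got$F[got$effect == "sess"], F_w, tolerance = 1e-8)
  expect_equal(got$F[got$effect == "grp:sess"], F_gw, tolerance = 1e-8)
  expect_equal(got$p[got$effect == "grp"],
               pf(F_grp, G - 1, S - G, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_equal(got$df_num[got$effect == "grp:sess"], 3)
  expect_equal(got$df_den[got$effect == "grp:sess"], 18)

  # group F on a 2-level within design equals squared t on subject means
  d2 <- d[d$sess %in% c("w1", "w2"), ]
  got2 <- split_plot_anova(d2, "y", "subj", "sess", "grp")
  sm <- tapply(d2$y, d2$subj, mean)
  gg <- ifelse(names(sm) %in% sprintf("s%d", 1:4), "paired", "unpaired")
  tt <- two_sample_t(sm[gg == "paired"], sm[gg == "unpaired"])
  expect_equal(got2$F[got2$effect == "grp"], tt$t^2, tolerance = 1e-8)

  # degenerate constant response -> all F = 0, p = 1
  d$y <- 5
  got0 <- split_plot_anova(d, "y", "subj", "sess", "grp")
  expect_true(all(got0$F == 0))
  expect_true(all(got0$p == 1))

  # unbalanced designs are rejected, not approximated
  expect_error(split_plot_anova(d[-1, ], "y", "subj", "sess", "grp"),
               "unbalanced|unsupported")
})

test_that("split-plot ANOVA holds its nominal type-I error rate", {
  set.seed(42)
  rej <- 0
  for (r in 1:1000) {
    d <- expand.grid(subj = 1:16, sess = 1:4)
    d$grp <- ifelse(d$subj <= 8, "a", "b")
    d$y <- rnorm(64)
    tab <- split_plot_anova(d, "y", "subj", "sess", "grp")
    rej <- rej + (tab$p[tab$effect == "grp"] < 0.05)
  }
  expect_gte(rej / 1000, 0.035)
  expect_lte(rej / 1000, 0.065)
})

test_that("Bonferroni threshold is alpha/m", {
  expect_equal(bonferroni(0.05, 12), 0.05 / 12)
  expect_equal(round(bonferroni(0.05, 12), 6), 0.004167)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.01, 5), 0.002)
  # monotone decreasing in m
  expect_true(all(diff(vapply(1:20, bonferroni, alpha = 0.05,
                              numeric(1))) < 0))
  expect_error(bonferroni(0.05, 0), "positive")
  expect_error(bonferroni(1.2, 3), "alpha")
})
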