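test_that("kinetics validate and absorbing dynamics stay put", {
  labs <- behavior_labels()
  # identity transition matrix + freeze start -> 87 x freeze
  init <- setNames(rep(0, 13), labs); init["freeze"] <- 1
  kin_abs <- behavior_kinetics(transition = diag(13), dwell = 1,
                               initial = init)
  kin <- list(baseline = kin_abs, cue = kin_abs, late = kin_abs)
  expect_identical(simulate_trial_labels(kin, seed = 2),
                   rep("freeze", 87))
  # determinism
  kin2 <- default_kinetics("paired", "conditioning")
  expect_identical(simulate_trial_labels(kin2, seed = 5),
                   simulate_trial_labels(kin2, seed = 5))
  expect_false(identical(simulate_trial_labels(kin2, seed = 5),
                         simulate_trial_labels(kin2, seed = 6)))
  # validation
  bad <- diag(13); bad[1, 1] <- 0.5
  expect_error(behavior_kinetics(transition = bad), "sum to 1")
  expect_error(behavior_kinetics(occupancy = setNames(rep(1 / 13, 13), labs),
                                 dwell = 0.5), "dwell")
  occ <- setNames(rep(1 / 13, 13), labs)
  expect_error(behavior_kinetics(occupancy = occ * 2), "simplex")
})

test_that("long-run occupancy matches the kernel's stationary distribution", {
  set.seed(3)
  P <- matrix(runif(169), 13, 13)
  P <- P / rowSums(P)
  kin <- behavior_kinetics(transition = P, dwell = 1)
  s <- simulate_chain(kin, 10000, seed = 8)
  emp <- as.numeric(table(factor(s, levels = behavior_labels())) / 10000)
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, 1]); stat <- stat / sum(stat)
  expect_lt(sum(abs(emp - stat)), 0.05)
})

test_that("the default experiment reproduces the design cardinalities", {
  exp <- cached_default_experiment(seed = 1)
  expect_length(exp$trials, 256)        # 32 rats x 2 sessions x 4 trials
  expect_length(exp$events, 64)
  expect_equal(nrow(exp$metadata), 32)
  expect_equal(as.integer(table(exp$metadata$group)), c(16L, 16L))
  expect_equal(as.integer(table(exp$metadata$sex, exp$metadata$group)),
               rep(8L, 4))
  expect_equal(sort(unique(exp$metadata$intensity_mA)), c(0.35, 0.5))
  # observers differ across the 4 trials of a session
  first <- Filter(function(tr) tr$rat_id == "r01" &&
                    tr$session_type == "conditioning", exp$trials)
  expect_length(unique(vapply(first, `[[`, "", "observer_id")), 4)
  # determinism of the full dataset
  exp2 <- simulate_experiment(sim_config(seed = 1))
  expect_identical(lapply(exp$trials, `[[`, "labels"),
                   lapply(exp2$trials, `[[`, "labels"))
  expect_equal(exp$events[[1]]$time_s, exp2$events[[1]]$time_s)
})

test_that("null effect size makes paired and unpaired kinetics identical", {
  kp <- default_kinetics("paired", "conditioning", effect_size = "none")
  ku <- default_kinetics("unpaired", "conditioning", effect_size = "none")
  expect_equal(kp, ku)
  ks <- default_kinetics("paired", "conditioning", effect_size = "strong")
  expect_false(isTRUE(all.equal(kp$cue$initial, ks$cue$initial)))
})

test_that("moderate effect elevates paired cue freezing in nearly all seeds", {
  hits <- vapply(1:20, function(seed) {
    freeze_pct <- function(group) {
      kin <- default_kinetics(group, "conditioning")
      mean(vapply(1:16, function(i) {
        s <- simulate_trial_labels(kin, seed = seed * 100 + i)
        mean(s[period_frames("cue")] == "freeze")
      }, numeric(1)))
    }
    freeze_pct("paired") > freeze_pct("unpaired")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Poisson poke streams have the right mass and respect cues", {
  # zero rate -> empty stream
  log0 <- simulate_pokes(0, 0.5, cue_onsets = 100, duration = 600, seed = 1)
  expect_equal(sum(log0$event == "poke"), 0)
  # 60/min over 10 min -> ~600 events (within 3 sd for most seeds)
  counts <- vapply(1:20, function(s) {
    sum(simulate_pokes(60, 0, cue_onsets = numeric(0), duration = 600,
                       seed = s)$event == "poke")
  }, numeric(1))
  expect_gte(mean(abs(counts - 600) <= 3 * sqrt(600)), 0.99)
  # full suppression -> no pokes inside any cue interval
  log1 <- simulate_pokes(60, 1, cue_onsets = c(100, 300), duration = 600,
                         seed = 2)
  pokes <- log1$time_s[log1$event == "poke"]
  expect_false(any((pokes >= 100 & pokes < 110) |
                     (pokes >= 300 & pokes < 310)))
  expect_error(simulate_pokes(60, 0.5, 100, duration = -5), "duration")
  expect_error(simulate_pokes(-1, 0.5, 100, duration = 5), "rate")
})

test_that("comparison trials give every observer the same latent sequence", {
  cmp <- simulate_comparison_trials(n_trials = 2, n_observers = 3,
                                    flip_prob = 0, confuse_prob = 0,
                                    seed = 4)
  expect_length(cmp, 6)
  t1 <- Filter(function(x) x$trial_index == 1, cmp)
  expect_identical(t1[[1]]$labels, t1[[2]]$labels)
  expect_identical(t1[[1]]$labels, t1[[3]]$labels)
  # with noise, observers disagree but determinism holds
  cmp2 <- simulate_comparison_trials(seed = 4)
  cmp3 <- simulate_comparison_trials(seed = 4)
  expect_identical(lapply(cmp2, `[[`, "labels"),
                   lapply(cmp3, `[[`, "labels"))
  rel <- reliability_report(cmp2)
  expect_lt(rel$mean_percent, 100)
  expect_gt(rel$mean_percent, 50)
})
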