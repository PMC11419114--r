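test_that("the discriminant matches the closed-form two-Gaussian solution", {
  # class means (0,0) and (2,0), identity pooled covariance:
  # w proportional to (2,0), boundary at x1 = 1
  set.seed(11)
  b1 <- scale(matrix(rnorm(200), 100, 2), center = TRUE, scale = FALSE)
  b2 <- scale(matrix(rnorm(200), 100, 2), center = TRUE, scale = FALSE)
  # whiten so the pooled within-class covariance is exactly the identity
  W <- solve(chol(crossprod(rbind(b1, b2)) / (200 - 2)))
  X <- rbind(b1 %*% W, sweep(b2 %*% W, 2, c(-2, 0)))
  y <- rep(c("a", "b"), each = 100)
  fit <- fit_lda(X, y)
  dirn <- fit$w / sqrt(sum(fit$w^2))
  expect_equal(abs(dirn[1]), 1, tolerance = 1e-6)
  expect_equal(dirn[2], 0, tolerance = 1e-6)
  expect_equal(unname(predict(fit, c(0.9, 5))), "a")
  expect_equal(unname(predict(fit, c(1.1, -5))), "b")

  # degenerate separable case: zero within-class covariance
  Xd <- rbind(matrix(0, 5, 3), matrix(1, 5, 3))
  yd <- rep(c("a", "b"), each = 5)
  fitd <- fit_lda(Xd, yd)
  expect_equal(unname(predict(fitd, Xd)), yd)

  expect_error(fit_lda(Xd, rep("a", 10)), "two classes")
  expect_error(fit_lda(Xd * NA, yd), "finite")
})

test_that("predictions match reference discriminants on shared data", {
  skip_if_not_installed("MASS")
  # full-rank case: agree with MASS::lda under equal priors
  set.seed(12)
  n <- 60
  Xtr <- rbind(matrix(rnorm(n * 5), n, 5),
               matrix(rnorm(n * 5, mean = 0.8), n, 5))
  colnames(Xtr) <- paste0("V", 1:5)
  ytr <- rep(c("paired", "unpaired"), each = n)
  Xte <- rbind(matrix(rnorm(200 * 5), 200, 5),
               matrix(rnorm(200 * 5, mean = 0.8), 200, 5))
  colnames(Xte) <- paste0("V", 1:5)
  fit <- fit_lda(Xtr, ytr)
  ref <- MASS::lda(Xtr, grouping = ytr, prior = c(0.5, 0.5))
  agree <- mean(predict(fit, Xte) ==
                  as.character(predict(ref, as.data.frame(Xte))$class))
  expect_gte(agree, 0.95)

  # singular case (n << p, like 64 x 1044): agree with an independent
  # generalized-inverse discriminant built from MASS::ginv
  set.seed(13)
  p <- 1044
  Xs <- rbind(matrix(rnorm(32 * p), 32, p),
              matrix(rnorm(32 * p, mean = 0.15), 32, p))
  ys <- rep(c("paired", "unpaired"), each = 32)
  tr_idx <- c(1:26, 33:58)
  fit2 <- fit_lda(Xs[tr_idx, ], ys[tr_idx])
  mu1 <- colMeans(Xs[1:26, ]); mu2 <- colMeans(Xs[33:58, ])
  Xc <- rbind(sweep(Xs[1:26, ], 2, mu1), sweep(Xs[33:58, ], 2, mu2))
  S <- crossprod(Xc) / (52 - 2)
  d <- mu2 - mu1
  w_ref <- MASS::ginv(S) %*% d
  score_ref <- Xs[-tr_idx, ] %*% w_ref - sum(w_ref * (mu1 + mu2)) / 2
  pred_ref <- ifelse(score_ref > 0, "unpaired", "paired")
  agree2 <- mean(predict(fit2, Xs[-tr_idx, ]) == pred_ref)
  expect_gte(agree2, 0.95)
})

test_that("predictions are invariant to feature order and affine maps", {
  set.seed(14)
  X <- rbind(matrix(rnorm(40 * 5), 40, 5),
             matrix(rnorm(40 * 5, mean = 0.7), 40, 5))
  y <- rep(c("a", "b"), each = 40)
  Xte <- matrix(rnorm(30 * 5), 30, 5)
  base_pred <- predict(fit_lda(X, y), Xte)

  perm <- sample(5)
  expect_identical(predict(fit_lda(X[, perm], y), Xte[, perm]), base_pred)

  A <- matrix(rnorm(25), 5, 5) + diag(5) * 2  # invertible w.h.p.
  expect_identical(predict(fit_lda(X %*% A, y), Xte %*% A), base_pred)
})

test_that("repeated CV is deterministic, bounded, and exact on separable data", {
  set.seed(15)
  X <- rbind(matrix(rnorm(32 * 6), 32, 6),
             matrix(rnorm(32 * 6, mean = 30), 32, 6))
  y <- rep(c("paired", "unpaired"), each = 32)
  cv <- repeated_cv(X, y, reps = 10, seed = 3)
  expect_equal(cv$mean, 1)
  expect_true(all(cv$accuracies >= 0 & cv$accuracies <= 1))
  expect_equal(cv$mean, mean(cv$accuracies))
  expect_equal(cv$sem, sd(cv$accuracies) / sqrt(10))

  cv2 <- repeated_cv(X, y, reps = 10, seed = 3)
  expect_identical(cv$accuracies, cv2$accuracies)
  # different seeds give different fold sequences (visible on
  # non-separable data)
  Xo <- rbind(matrix(rnorm(32 * 6), 32, 6),
              matrix(rnorm(32 * 6, mean = 0.4), 32, 6))
  cv3 <- repeated_cv(Xo, y, reps = 10, seed = 4)
  cv4 <- repeated_cv(Xo, y, reps = 10, seed = 5)
  expect_false(identical(cv3$accuracies, cv4$accuracies))

  # random labels on identical rows sit at chance exactly
  Xn <- matrix(1, 20, 4)
  cvn <- repeated_cv(Xn, session_shuffle(rep(c("a", "b"), 10), seed = 1),
                     k = 5, reps = 20, seed = 9)
  expect_true(abs(cvn$mean - 0.5) <= max(3 * cvn$sem, 1e-12))

  expect_error(repeated_cv(X, y, k = 1), "k must be")
  expect_warning(repeated_cv(X[c(1:4, 33:36), ], y[c(1:4, 33:36)],
                             k = 5, reps = 2, seed = 1),
                 "unstratified")
})

test_that("session shuffle preserves the label multiset and mixes uniformly", {
  y <- rep(c("paired", "unpaired"), each = 16)
  for (seed in 1:5) {
    ys <- session_shuffle(y, seed = seed)
    expect_equal(sort(ys), sort(y))
  }
  expect_identical(session_shuffle(y, seed = 8), session_shuffle(y, seed = 8))
  # expected fraction of fixed points is 1/2 for balanced binary labels
  set.seed(16)
  frac <- mean(replicate(10000, mean(session_shuffle(y) == y)))
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("temporal shuffle permutes columns within session only", {
  exp <- cached_default_experiment(seed = 1)
  ft <- cached_default_features(seed = 1)
  parts <- split_features(ft)
  Xs <- temporal_shuffle(parts$X, seed = 5)
  expect_equal(dim(Xs), dim(parts$X))
  # per-behavior row sums invariant for every session
  for (i in c(1, 17, 64)) {
    before <- rowSums(matrix(parts$X[i, ], 12, 87, byrow = TRUE))
    after <- rowSums(matrix(Xs[i, ], 12, 87, byrow = TRUE))
    expect_equal(after, before)
  }
  expect_identical(temporal_shuffle(parts$X, seed = 5), Xs)
  # a time-constant session is unchanged by any permutation
  flat_const <- rep(rep(1 / 12, 12), each = 87)
  expect_equal(temporal_shuffle(matrix(flat_const, 1), seed = 99)[1, ],
               flat_const)
  expect_error(temporal_shuffle(parts$X[, 1:100]), "shape")
})

test_that("temporal shuffling preserves accuracy when totals carry the signal", {
  # Sessions whose group signal lives purely in per-behavior totals, with
  # uniformly random temporal placement: the shuffled data are equal in
  # law to the intact data, so accuracy must be preserved. The comparison
  # is averaged over replicate datasets because a single dataset's
  # achieved accuracy fluctuates beyond the CV-repetition SEM.
  diffs <- vapply(1:3, function(rep) {
    set.seed(200 + rep)
    make_row <- function(mean_f) {
      mat <- matrix(0, 12, 10)
      n_f <- pmin(pmax(rpois(1, mean_f), 0), 8)
      idx <- sample(10)
      if (n_f > 0) mat[1, idx[seq_len(n_f)]] <- 1
      mat[3, idx[(n_f + 1):(n_f + 2)]] <- 1
      as.vector(t(mat))
    }
    X <- rbind(t(sapply(1:128, function(i) make_row(5))),
               t(sapply(1:128, function(i) make_row(2))))
    y <- rep(c("paired", "unpaired"), each = 128)
    cv_int <- repeated_cv(X, y, reps = 20, seed = rep)
    cv_ts <- repeated_cv(
      temporal_shuffle(X, seed = rep + 50, n_behaviors = 12, n_frames = 10),
      y, reps = 20, seed = rep)
    cv_int$mean - cv_ts$mean
  }, numeric(1))
  expect_true(all(abs(diffs) < 0.035))
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("feature subsets select the documented period x category blocks", {
  ft <- cached_default_features(seed = 1)
  X <- split_features(ft)$X
  expect_equal(ncol(subset_features(X)), 1044)
  expect_equal(ncol(subset_features(X, "cue", "Immobile")), 100)
  expect_equal(ncol(subset_features(X, "cue", "Horizontal")), 100)
  expect_equal(ncol(subset_features(X, "cue", "Vertical")), 250)
  expect_equal(ncol(subset_features(X, "cue", "Reward")), 100)
  expect_equal(ncol(subset_features(X, "post", "Vertical")), 60)
  # groom appears in no category subset
  all_cats <- subset_features(X, "all", names(behavior_categories()))
  expect_equal(ncol(all_cats), 11 * 87)
  expect_false(any(grepl("^groom", colnames(all_cats))))
  expect_true(any(grepl("^groom", colnames(X))))
  # values, not just counts: cue x Immobile equals the hand-picked block
  manual <- X[, c(26:75, 87 + 26:75)]
  expect_equal(unname(subset_features(X, "cue", "Immobile")),
               unname(manual))
  expect_error(subset_features(X, "cue", "Aerial"), "unknown")
})

test_that("training accuracy dominates held-out accuracy when n << p", {
  ft <- cached_default_features(seed = 1)
  parts <- split_features(ft)
  fit <- fit_lda(parts$X, parts$meta$group)
  train_acc <- mean(predict(fit, parts$X) == parts$meta$group)
  cv <- repeated_cv(parts$X, parts$meta$group, reps = 20, seed = 6)
  expect_gte(train_acc, cv$mean)
})
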