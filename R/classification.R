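#' Fit a two-class linear discriminant
#'
#' Linear discriminant analysis from class means and pooled within-class
#' covariance, with equal class priors. With many more features than
#' sessions (64 x 1044) the pooled covariance is singular, so the default
#' discriminant uses its Moore-Penrose pseudo-inverse, computed via the
#' thin SVD of the within-class-centered data (the standard pseudo-linear
#' discriminant). If the pseudo-inverse direction carries no signal at all
#' (the mean difference is orthogonal to the range of the pooled
#' covariance, e.g. zero within-class variance), the raw mean difference
#' is used instead, so perfectly separated degenerate data are still
#' separated. Shrinkage
#' (`(1-gamma) S + gamma (tr(S)/p) I`) and diagonal modes are available.
#'
#' @param X Numeric matrix, sessions x features (finite values).
#' @param y Two-level grouping vector; levels are taken in
#'   `sort(unique(y))` order.
#' @param regularizer `"pseudo"` (default), `"shrinkage"` or `"diag"`.
#' @param gamma Shrinkage weight in `[0, 1]` (shrinkage mode only).
#' @return Object of class `eth_lda` with elements `classes`, `means`
#'   (2 x p), `w` (discriminant vector), `threshold`, `regularizer`.
#' @export
fit_lda <- function(X, y, regularizer = c("pseudo", "shrinkage", "diag"),
                    gamma = 0.5) {
  regularizer <- match.arg(regularizer)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("features must be finite", call. = FALSE)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) {
    stop("exactly two classes are required, got ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  if (min(table(y)) < 2) stop("each class needs >= 2 rows", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  mu1 <- colMeans(X[y == classes[1], , drop = FALSE])
  mu2 <- colMeans(X[y == classes[2], , drop = FALSE])
  d <- mu2 - mu1
  Xc <- X
  Xc[y == classes[1], ] <- sweep(X[y == classes[1], , drop = FALSE], 2, mu1)
  Xc[y == classes[2], ] <- sweep(X[y == classes[2], , drop = FALSE], 2, mu2)
  df <- n - 2
  w <- switch(regularizer,
    pseudo = {
      sv <- svd(Xc)
      tol <- max(n, p) * .Machine$double.eps * max(sv$d, 0)
      keep <- sv$d > tol
      if (!any(keep)) {
        d  # zero pooled covariance: discriminate on the mean difference
      } else {
        V <- sv$v[, keep, drop = FALSE]
        proj <- crossprod(V, d)                       # V'd
        w_range <- as.vector(V %*% (proj * df / sv$d[keep]^2))  # S+ d
        # fall back to the raw mean difference if the pooled covariance
        # carries no discriminating signal at all (d orthogonal to its
        # range, e.g. identical duplicated points per class)
        if (sum(w_range * d) <= 0) d else w_range
      }
    },
    shrinkage = {
      if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]", call. = FALSE)
      S <- crossprod(Xc) / df
      tr <- sum(diag(S))
      if (tr == 0) d
      else {
        Tm <- (1 - gamma) * S
        diag(Tm) <- diag(Tm) + gamma * tr / p
        as.vector(solve(Tm, d))
      }
    },
    diag = {
      s2 <- colSums(Xc^2) / df
      floor_v <- 1e-12 * max(s2, 1)
      d / pmax(s2, floor_v)
    }
  )
  structure(
    list(classes = classes, means = rbind(mu1, mu2), w = w,
         threshold = sum(w * (mu1 + mu2)) / 2, regularizer = regularizer),
    class = "eth_lda"
  )
}

#' Predict class membership from a fitted discriminant
#'
#' @param object An `eth_lda` model.
#' @param newdata Matrix (rows = sessions) or vector of features.
#' @param ... Unused.
#' @return Character vector of predicted classes; scores exactly on the
#'   boundary go to the first class.
#' @export
predict.eth_lda <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  scores <- as.vector(newdata %*% object$w)
  ifelse(scores > object$threshold, object$classes[2], object$classes[1])
}

#' Shuffle group labels across sessions
#'
#' Uniformly random permutation of the label vector (class counts are
#' preserved); destroys the label-ethogram association and so provides the
#' classification null.
#'
#' @param y Label vector.
#' @param seed Optional integer; when given, the shuffle is reproducible
#'   and the caller's RNG stream is left untouched.
#' @return Permuted copy of `y`.
#' @export
session_shuffle <- function(y, seed = NULL) {
  if (length(y) == 0) stop("labels must be non-empty", call. = FALSE)
  if (is.null(seed)) y[sample.int(length(y))]
  else .with_seed(seed, y[sample.int(length(y))])
}

#' Shuffle temporal structure within each session
#'
#' For each session (row) independently, one random permutation of the 87
#' frame columns is applied jointly to all 12 behavior rows of the
#' unflattened ethogram, then re-flattened. Per-behavior totals per session
#' are invariant; which behaviors occurred (and how much) is preserved
#' while when they occurred is destroyed.
#'
#' @param X Feature matrix, sessions x (n_behaviors * n_frames), flattened
#'   behavior-major.
#' @param seed Optional integer for reproducibility.
#' @param n_behaviors,n_frames Shape of the unflattened ethogram; `X` must
#'   have exactly `n_behaviors * n_frames` columns.
#' @return Matrix of the same shape.
#' @export
temporal_shuffle <- function(X, seed = NULL, n_behaviors = 12,
                             n_frames = frames_per_trial()) {
  X <- as.matrix(X)
  if (ncol(X) != n_behaviors * n_frames) {
    stop("cannot infer ethogram shape: expected ", n_behaviors * n_frames,
         " columns (", n_behaviors, " behaviors x ", n_frames, " frames), ",
         "got ", ncol(X), call. = FALSE)
  }
  do_shuffle <- function() {
    out <- X
    for (i in seq_len(nrow(X))) {
      perm <- sample.int(n_frames)
      idx <- rep((seq_len(n_behaviors) - 1) * n_frames, each = n_frames) +
        rep(perm, n_behaviors)
      out[i, ] <- X[i, idx]
    }
    out
  }
  if (is.null(seed)) do_shuffle() else .with_seed(seed, do_shuffle())
}

#' Restrict features to a period and/or behavior-category subset
#'
#' @param X Flattened feature matrix (sessions x 1044, behavior-major in
#'   the canonical [scored_behaviors()] order).
#' @param period `"baseline"`, `"cue"`, `"post"` or `"all"`.
#' @param categories `"all"`, or a character vector of category names from
#'   [behavior_categories()] (grooming belongs to no category and is
#'   excluded from every category subset).
#' @return Reduced feature matrix (e.g. cue x Immobile keeps
#'   2 x 50 = 100 columns).
#' @export
subset_features <- function(X, period = "all", categories = "all") {
  X <- as.matrix(X)
  nf <- frames_per_trial()
  behaviors <- scored_behaviors()
  if (ncol(X) != length(behaviors) * nf) {
    stop("expected ", length(behaviors) * nf, " feature columns",
         call. = FALSE)
  }
  frames <- period_frames(period)
  if (identical(categories, "all")) {
    keep_beh <- behaviors
  } else {
    cats <- behavior_categories()
    bad <- setdiff(categories, names(cats))
    if (length(bad) > 0) {
      stop("unknown behavior category: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    keep_beh <- unique(unlist(cats[categories]))
  }
  b_idx <- match(keep_beh, behaviors)
  cols <- unlist(lapply(b_idx, function(b) (b - 1) * nf + frames))
  if (length(cols) == 0) stop("empty feature subset", call. = FALSE)
  X[, cols, drop = FALSE]
}

#' Repeated stratified 10-fold cross-validated LDA accuracy
#'
#' For each of `reps` repetitions, draws a fresh random stratified
#' partition of the sessions into `k` folds, trains the discriminant on
#' k-1 folds and scores the held-out fold; the repetition's accuracy
#' (1 minus the classification loss) is the mean over folds of the
#' held-out fraction correct. With `shuffle_labels = TRUE` the labels are
#' freshly permuted at every repetition ([session_shuffle()]), giving the
#' session-shuffled null. Fully reproducible from `seed`.
#'
#' @inheritParams fit_lda
#' @param k Number of folds (default 10).
#' @param reps Number of repetitions (default 100).
#' @param seed Integer seed; the caller's RNG stream is untouched.
#' @param shuffle_labels Permute labels each repetition (null condition).
#' @return Object of class `cv_result`: list with `accuracies` (length
#'   `reps`), `mean`, `sem` (sample SD / sqrt(reps)), `k`, `reps`, `seed`,
#'   `condition`.
#' @export
repeated_cv <- function(X, y, k = 10, reps = 100, seed = 1,
                        shuffle_labels = FALSE,
                        regularizer = "pseudo", gamma = 0.5) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (nrow(X) != length(y)) stop("X rows and y length differ", call. = FALSE)
  counts <- table(y)
  stratified <- all(counts >= k)
  if (!stratified) {
    if (length(y) < k) stop("fewer rows than folds", call. = FALSE)
    warning("class counts below k; falling back to unstratified folds")
  }
  assign_folds <- function(lab) {
    fold <- integer(length(lab))
    if (stratified) {
      for (cl in unique(lab)) {
        idx <- which(lab == cl)
        fold[idx[sample.int(length(idx))]] <-
          rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(length(lab))] <- rep_len(seq_len(k), length(lab))
    }
    fold
  }
  accs <- .with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      lab <- if (shuffle_labels) session_shuffle(y) else y
      fold <- assign_folds(lab)
      fold_acc <- vapply(seq_len(k), function(f) {
        test <- fold == f
        model <- fit_lda(X[!test, , drop = FALSE], lab[!test],
                         regularizer = regularizer, gamma = gamma)
        mean(predict(model, X[test, , drop = FALSE]) == lab[test])
      }, numeric(1))
      mean(fold_acc)
    }, numeric(1))
  })
  structure(
    list(accuracies = accs, mean = mean(accs),
         sem = stats::sd(accs) / sqrt(reps), k = k, reps = reps,
         seed = seed,
         condition = if (shuffle_labels) "session_shuffled" else "intact"),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean accuracy %.4f +/- %.4f SEM (%d reps, %d-fold)\n",
              x$condition, x$mean, x$sem, x$reps, x$k))
  invisible(x)
}

#' Full classification analysis grid
#'
#' Reproduces the study's grid of discriminant analyses on a session
#' feature table: \{intact, session-shuffled, temporal-shuffled\} x
#' \{all, baseline, cue, post\} periods on the full behavior set, plus the
#' intact-data behavior-category subsets (Immobile, Horizontal, Vertical,
#' Reward) during the cue and post periods. Temporal shuffling is applied
#' within the analyzed period, so each cell destroys only its own window's
#' temporal structure. Every cell reuses the same
#' root seed so fold partitions are matched across feature subsets, and
#' each cell's mean accuracy is tested against chance (0.5) with a
#' one-sample t-test.
#'
#' @param features Feature table from [feature_table()].
#' @param seed Integer root seed.
#' @param reps Repetitions per cell (default 100).
#' @param regularizer Passed to [fit_lda()].
#' @return List with `summary` (data frame: `condition`, `period`,
#'   `categories`, `n_features`, `mean_accuracy`, `sem`, `t_vs_chance`,
#'   `p_vs_chance`) and `results` (named list of `cv_result`).
#' @export
run_full_analysis <- function(features, seed = 1, reps = 100,
                              regularizer = "pseudo") {
  parts <- split_features(features)
  X <- parts$X
  y <- parts$meta$group
  grid <- rbind(
    expand.grid(condition = c("intact", "session_shuffled",
                              "temporal_shuffled"),
                period = c("all", "baseline", "cue", "post"),
                categories = "all", stringsAsFactors = FALSE),
    expand.grid(condition = "intact", period = c("cue", "post"),
                categories = names(behavior_categories()),
                stringsAsFactors = FALSE)
  )
  results <- list()
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cond <- grid$condition[i]
    Xs <- subset_features(X, period = grid$period[i],
                          categories = if (grid$categories[i] == "all") "all"
                                       else grid$categories[i])
    if (cond == "temporal_shuffled") {
      # shuffle time within the analyzed period so only that window's
      # temporal structure is destroyed
      Xs <- temporal_shuffle(Xs, seed = seed + 1, n_behaviors = 12,
                             n_frames = length(period_frames(grid$period[i])))
    }
    cv <- repeated_cv(Xs, y, reps = reps, seed = seed,
                      shuffle_labels = cond == "session_shuffled",
                      regularizer = regularizer)
    cv$condition <- cond
    tt <- one_sample_t(cv$accuracies, 0.5)
    key <- paste(cond, grid$period[i], grid$categories[i], sep = ".")
    results[[key]] <- cv
    rows[[i]] <- data.frame(
      condition = cond, period = grid$period[i],
      categories = grid$categories[i], n_features = ncol(Xs),
      mean_accuracy = cv$mean, sem = cv$sem, t_vs_chance = tt$t,
      p_vs_chance = tt$p
    )
  }
  list(summary = do.call(rbind, rows), results = results)
}
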