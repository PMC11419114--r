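#' Percent identical observations between two observers
#'
#' @param a,b Equal-length label sequences.
#' @return 100 x (number of positions with identical labels) / length.
#' @export
pairwise_agreement <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1) {
    stop("label sequences must have equal, positive length", call. = FALSE)
  }
  100 * mean(a == b)
}

.split_comparison_trials <- function(trials) {
  key <- vapply(trials, function(tr) {
    paste(tr$rat_id, tr$session_id, tr$trial_index, sep = "\x1f")
  }, "")
  split(trials, key)
}

#' Inter-observer reliability report
#'
#' For comparison trials scored by several observers, computes percent
#' identical observations for every unordered observer pair (pooled over
#' all frames the pair both scored) and the overall mean.
#'
#' @param trials List of `trial_frames`; each (rat, session, trial) must be
#'   scored by >= 2 observers. Trials with a single observer are dropped
#'   with a warning.
#' @return List with `pairwise` (data frame: `observer_1`, `observer_2`,
#'   `n_frames`, `percent_identical`; observer_1 is the lower observer ID),
#'   and `mean_percent` (frame-weighted mean over pairs).
#' @export
reliability_report <- function(trials) {
  groups <- .split_comparison_trials(trials)
  tallies <- list()
  for (g in groups) {
    obs <- vapply(g, `[[`, "", "observer_id")
    if (length(obs) < 2) {
      warning("trial scored by a single observer excluded from reliability")
      next
    }
    ord <- order(obs)
    g <- g[ord]; obs <- obs[ord]
    for (i in seq_len(length(g) - 1)) {
      for (j in seq(i + 1, length(g))) {
        key <- paste(obs[i], obs[j], sep = "\x1f")
        same <- sum(g[[i]]$labels == g[[j]]$labels)
        prev <- tallies[[key]]
        if (is.null(prev)) prev <- c(0, 0)
        tallies[[key]] <- prev + c(same, frames_per_trial())
      }
    }
  }
  if (length(tallies) == 0) stop("no multi-observer trials", call. = FALSE)
  pairs <- do.call(rbind, strsplit(names(tallies), "\x1f", fixed = TRUE))
  tal <- do.call(rbind, tallies)
  pairwise <- data.frame(
    observer_1 = pairs[, 1], observer_2 = pairs[, 2],
    n_frames = tal[, 2], percent_identical = 100 * tal[, 1] / tal[, 2],
    stringsAsFactors = FALSE
  )
  rownames(pairwise) <- NULL
  pairwise <- pairwise[order(pairwise$observer_1, pairwise$observer_2), ]
  list(
    pairwise = pairwise,
    mean_percent = 100 * sum(tal[, 1]) / sum(tal[, 2])
  )
}

#' Agreement stratified by number of behaviors present
#'
#' A trial's behavior count n is the number of distinct non-background
#' behaviors in the union of all observers' labels for that trial (an
#' observer-independent definition). Agreement at each n is the mean
#' percent identical over all observer-pair x trial comparisons with that
#' n.
#'
#' @inheritParams reliability_report
#' @return Data frame: `n_behaviors`, `n_comparisons`, `mean_percent`.
#' @export
agreement_by_behavior_count <- function(trials) {
  groups <- .split_comparison_trials(trials)
  rows <- list()
  for (g in groups) {
    obs <- vapply(g, `[[`, "", "observer_id")
    if (length(obs) < 2) {
      warning("trial scored by a single observer excluded from reliability")
      next
    }
    n_beh <- length(setdiff(unique(unlist(lapply(g, `[[`, "labels"))),
                            "background"))
    for (i in seq_len(length(g) - 1)) {
      for (j in seq(i + 1, length(g))) {
        rows[[length(rows) + 1]] <- data.frame(
          n_behaviors = n_beh,
          percent = pairwise_agreement(g[[i]]$labels, g[[j]]$labels)
        )
      }
    }
  }
  if (length(rows) == 0) stop("no multi-observer trials", call. = FALSE)
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(percent ~ n_behaviors, df,
                   function(x) c(n = length(x), mean = mean(x)))
  data.frame(
    n_behaviors = agg$n_behaviors,
    n_comparisons = agg$percent[, "n"],
    mean_percent = agg$percent[, "mean"]
  )
}

#' Observer-pair confusion matrix
#'
#' Every single-frame judgment of every unordered observer pair increments
#' one cell: the row is the label assigned by the pair's lower-ID observer,
#' the column the higher-ID observer's label. Perfect agreement puts all
#' mass on the diagonal.
#'
#' @inheritParams reliability_report
#' @return List with `counts` (13 x 13 integer matrix in canonical label
#'   order) and `row_percent` (rows normalized to 100; all-zero rows stay
#'   zero).
#' @export
confusion_matrix <- function(trials) {
  labs <- behavior_labels()
  counts <- matrix(0L, 13, 13, dimnames = list(labs, labs))
  groups <- .split_comparison_trials(trials)
  any_pair <- FALSE
  for (g in groups) {
    obs <- vapply(g, `[[`, "", "observer_id")
    if (length(obs) < 2) {
      warning("trial scored by a single observer excluded from reliability")
      next
    }
    ord <- order(obs)
    g <- g[ord]
    any_pair <- TRUE
    for (i in seq_len(length(g) - 1)) {
      for (j in seq(i + 1, length(g))) {
        t1 <- table(factor(g[[i]]$labels, levels = labs),
                    factor(g[[j]]$labels, levels = labs))
        counts <- counts + as.matrix(t1)
      }
    }
  }
  if (!any_pair) stop("no multi-observer trials", call. = FALSE)
  rs <- rowSums(counts)
  row_percent <- 100 * counts / ifelse(rs > 0, rs, 1)
  list(counts = counts, row_percent = row_percent)
}
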