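#' 1-s analysis windows tiling the 87 frames
#'
#' Five-frame (1-s) windows 1-5, 6-10, ..., 81-85 plus a trailing 2-frame
#' window 86-87 (flagged `partial`). Baseline contributes windows 1-5
#' through 21-25, the cue period 26-30 through 71-75, the post period
#' 76-80, 81-85 and 86-87.
#'
#' @return Data frame: `window` (label), `first`, `last`, `partial`.
#' @export
window_layout <- function() {
  first <- seq(1, 86, by = 5)
  last <- pmin(first + 4, frames_per_trial())
  data.frame(
    window = sprintf("f%02d-%02d", first, last),
    first = first, last = last,
    partial = (last - first + 1) < 5
  )
}

#' Pooled-variance two-sample t-test
#'
#' Student's (equal-variance) independent-samples t, two-tailed. When both
#' groups have zero variance: equal means give t = 0, p = 1; unequal means
#' give p = 0 with a warning.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  df <- length(x) + length(y) - 2
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = df, p = 1))
    warning("zero within-group variance with unequal means; p set to 0")
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = df, p = ht$p.value)
}

#' One-sample t-test
#'
#' Two-tailed Student's t with n-1 df. Zero-variance conventions: mean
#' equal to `mu` gives t = 0, p = 1; otherwise p = 0 with a warning.
#'
#' @param values Numeric vector, n >= 2.
#' @param mu Null-hypothesis mean.
#' @return List with `t`, `df`, `p`.
#' @export
one_sample_t <- function(values, mu) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  df <- length(values) - 1
  s <- stats::sd(values)
  if (s == 0) {
    if (mean(values) == mu) return(list(t = 0, df = df, p = 1))
    warning("zero variance with mean != mu; p set to 0")
    return(list(t = sign(mean(values) - mu) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(values, mu = mu)
  list(t = unname(ht$statistic), df = df, p = ht$p.value)
}

#' Windowed group comparisons for one behavior
#'
#' The unit of analysis is the rat: per rat and 1-s window, % behavior is
#' the mean of the behavior indicator over the rat's trials and the
#' window's frames, x100. Each window is then tested with a two-tailed
#' pooled-variance t-test between paired and unpaired rats; windows
#' reaching p < alpha are tagged with the direction of the difference
#' (these are the colored significance bars over the ethogram line plots).
#'
#' @param trials List of `trial_frames` with group metadata; both groups
#'   must contribute >= 2 rats.
#' @param behavior One of [scored_behaviors()].
#' @param alpha Significance level (default 0.05).
#' @return Data frame: one row per window with `behavior`, `window`,
#'   `first`, `last`, `partial`, `mean_paired`, `mean_unpaired`, `t`, `p`,
#'   `direction`.
#' @export
window_ttests <- function(trials, behavior, alpha = 0.05) {
  behavior <- match.arg(behavior, scored_behaviors())
  groups <- vapply(trials, `[[`, "", "group")
  if (any(is.na(groups))) {
    stop("all trials need group metadata", call. = FALSE)
  }
  wins <- window_layout()
  # per-rat mean indicator over trials x window frames
  rat_ids <- vapply(trials, `[[`, "", "rat_id")
  per_rat <- lapply(split(seq_along(trials), rat_ids), function(idx) {
    ind <- lapply(trials[idx], function(tr) trial_indicator(tr)[behavior, ])
    ind <- do.call(rbind, ind)
    pct <- vapply(seq_len(nrow(wins)), function(w) {
      100 * mean(ind[, wins$first[w]:wins$last[w]])
    }, numeric(1))
    list(group = groups[idx[1]], pct = pct)
  })
  g <- vapply(per_rat, `[[`, "", "group")
  if (sum(g == "paired") < 2 || sum(g == "unpaired") < 2) {
    stop("need at least 2 rats per group", call. = FALSE)
  }
  pct <- do.call(rbind, lapply(per_rat, `[[`, "pct"))
  out <- wins
  out$behavior <- behavior
  res <- lapply(seq_len(nrow(wins)), function(w) {
    tt <- two_sample_t(pct[g == "paired", w], pct[g == "unpaired", w])
    data.frame(
      mean_paired = mean(pct[g == "paired", w]),
      mean_unpaired = mean(pct[g == "unpaired", w]),
      t = tt$t, p = tt$p
    )
  })
  out <- cbind(out, do.call(rbind, res))
  out$direction <- ifelse(
    out$p >= alpha, "none",
    ifelse(out$mean_paired > out$mean_unpaired, "paired_greater",
           "unpaired_greater")
  )
  out[, c("behavior", "window", "first", "last", "partial", "mean_paired",
          "mean_unpaired", "t", "p", "direction")]
}

#' Balanced split-plot (mixed-design) ANOVA
#'
#' Classical sums-of-squares decomposition for a fully balanced design with
#' one within-subject factor and up to three crossed between-subject
#' factors: between effects are tested against the subject-within-groups
#' error, within and interaction effects against the subject x within
#' residual. No sphericity correction is applied. Unbalanced designs are
#' rejected.
#'
#' @param data Data frame in long format.
#' @param response,subject,within Column names (strings).
#' @param between Character vector of between-subject factor column names
#'   (1 to 3).
#' @return Data frame: `effect`, `F`, `df_num`, `df_den`, `p`. Degenerate
#'   zero-variance strata yield F = 0, p = 1.
#' @export
split_plot_anova <- function(data, response, subject, within, between) {
  stopifnot(length(between) >= 1, length(between) <= 3)
  cols <- c(response, subject, within, between)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("data is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(
    y = as.numeric(data[[response]]),
    subj = factor(data[[subject]]),
    w = factor(data[[within]])
  )
  for (i in seq_along(between)) d[[paste0("b", i)]] <- factor(data[[between[i]]])
  # balance: every cell of between x within has the same count, and every
  # subject appears once per within level
  bcols <- paste0("b", seq_along(between))
  cell <- table(do.call(interaction, c(d[bcols], d["w"])))
  if (length(unique(as.vector(cell))) != 1) {
    stop("unsupported design: cell counts are unbalanced", call. = FALSE)
  }
  if (any(table(d$subj, d$w) != 1)) {
    stop("unsupported design: each subject needs exactly one observation ",
         "per within-factor level", call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "y ~ (", paste(bcols, collapse = "*"), ") * w + Error(subj)"
  ))
  degenerate <- stats::var(d$y) == 0  # constant response: F = 0, p = 1
  fit <- stats::aov(fml, data = d)
  sm <- summary(fit)
  out <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    resid_row <- which(eff == "Residuals")
    df_den <- tab$Df[resid_row]
    for (r in setdiff(seq_len(nrow(tab)), resid_row)) {
      Fv <- tab$`F value`[r]
      pv <- tab$`Pr(>F)`[r]
      if (degenerate || !is.finite(Fv)) { Fv <- 0; pv <- 1 }  # 0/0 guard
      name <- eff[r]
      for (i in seq_along(between)) {
        name <- gsub(paste0("\\b", bcols[i], "\\b"), between[i], name)
      }
      name <- gsub("\\bw\\b", within, name)
      out[[length(out) + 1]] <- data.frame(
        effect = name, F = Fv, df_num = tab$Df[r], df_den = df_den, p = pv
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Familywise level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m` (e.g. 0.05/12 = 0.004167 for the 12 behaviors).
#' @export
bonferroni <- function(alpha, m) {
  if (length(m) != 1 || is.na(m) || m < 1) {
    stop("m must be a positive integer", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  alpha / m
}
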