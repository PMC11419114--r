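#' One-hot indicator matrix for a trial
#'
#' @param trial A [trial_frames()].
#' @return 13 x 87 binary matrix (rows = 12 behaviors + background in the
#'   canonical label order, columns = frames); every column sums to 1.
#' @export
trial_indicator <- function(trial) {
  stopifnot(inherits(trial, "trial_frames"))
  labs <- behavior_labels()
  mat <- matrix(0L, nrow = length(labs), ncol = frames_per_trial(),
                dimnames = list(labs, NULL))
  mat[cbind(match(trial$labels, labs), seq_len(frames_per_trial()))] <- 1L
  mat
}

#' Session ethogram: per-bin behavior fractions
#'
#' Averages the one-hot indicators of one rat-session's 4 trials into a
#' 12 x 87 matrix of behavior fractions (background dropped). With 4 trials
#' every cell is a quarter-multiple in \{0, 0.25, 0.5, 0.75, 1\}. Flattened
#' behavior-major (behavior 1 frames 1-87, then behavior 2, ...) it is the
#' 1044-element feature vector used for classification.
#'
#' @param trials List of exactly 4 `trial_frames` from one rat-session.
#' @return 12 x 87 numeric matrix with attributes `rat_id`, `session_id`,
#'   `session_type`, `group`, `sex`, `intensity_mA`, `n_trials`.
#' @export
session_array <- function(trials) {
  if (length(trials) != 4) {
    stop("a session array requires exactly 4 trials, got ", length(trials),
         call. = FALSE)
  }
  rat <- unique(vapply(trials, `[[`, "", "rat_id"))
  ses <- unique(vapply(trials, `[[`, "", "session_id"))
  if (length(rat) != 1 || length(ses) != 1) {
    stop("all 4 trials must come from the same rat-session", call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(trials, trial_indicator)) / length(trials)
  out <- acc[scored_behaviors(), , drop = FALSE]
  attr(out, "rat_id") <- rat
  attr(out, "session_id") <- ses
  attr(out, "session_type") <- trials[[1]]$session_type
  attr(out, "group") <- trials[[1]]$group
  attr(out, "sex") <- trials[[1]]$sex
  attr(out, "intensity_mA") <- trials[[1]]$intensity_mA
  attr(out, "n_trials") <- length(trials)
  out
}

#' Flatten a session ethogram to a feature vector
#'
#' Behavior-major order: behavior 1 frames 1-87, then behavior 2, etc.
#'
#' @param mat 12 x 87 session ethogram.
#' @return Numeric vector of length 1044, named `<behavior>.f<frame>`.
#' @export
flatten_session <- function(mat) {
  stopifnot(is.matrix(mat))
  v <- as.vector(t(mat))
  names(v) <- paste0(rep(rownames(mat), each = ncol(mat)), ".f",
                     rep(seq_len(ncol(mat)), nrow(mat)))
  v
}

#' Group ethogram: percent behavior per 200-ms bin
#'
#' For the selected trials, the percentage of trial-frames at each bin
#' carrying each label (background included, so every column sums to 100).
#'
#' @param trials List of `trial_frames`.
#' @param group,session_type,sex Optional filters (exact match).
#' @param intensity_mA Optional numeric filter.
#' @return 13 x 87 matrix of percentages.
#' @export
group_ethogram <- function(trials, group = NULL, session_type = NULL,
                           sex = NULL, intensity_mA = NULL) {
  keep <- vapply(trials, function(tr) {
    (is.null(group) || identical(tr$group, group)) &&
      (is.null(session_type) || identical(tr$session_type, session_type)) &&
      (is.null(sex) || identical(tr$sex, sex)) &&
      (is.null(intensity_mA) || isTRUE(tr$intensity_mA == intensity_mA))
  }, logical(1))
  sel <- trials[keep]
  if (length(sel) == 0) stop("selection matches no trials", call. = FALSE)
  acc <- Reduce(`+`, lapply(sel, trial_indicator))
  100 * acc / length(sel)
}

#' Restrict an ethogram to a trial period
#'
#' @param x A behavior x 87 matrix, or a flattened length-1044 vector
#'   (reshaped behavior-major).
#' @param period `"baseline"` (frames 1-25), `"cue"` (26-75), `"post"`
#'   (76-87) or `"all"`.
#' @return Matrix restricted to the period's columns (input shape is
#'   preserved: a flattened input returns a flattened output).
#' @export
segment_period <- function(x, period = c("baseline", "cue", "post", "all")) {
  period <- match.arg(period)
  frames <- period_frames(period)
  if (is.matrix(x)) {
    return(x[, frames, drop = FALSE])
  }
  if (length(x) != 12 * frames_per_trial()) {
    stop("flattened input must have length ", 12 * frames_per_trial(),
         call. = FALSE)
  }
  mat <- matrix(x, nrow = 12, byrow = TRUE)
  as.vector(t(mat[, frames, drop = FALSE]))
}

#' Session feature table for classification
#'
#' Builds the n-sessions x 1044 feature table (one [session_array()] per
#' rat-session, flattened) with metadata columns in front.
#'
#' @param trials List of `trial_frames` (4 per rat-session).
#' @return Data frame: `rat_id`, `session_id`, `session_type`, `group`,
#'   `sex`, `intensity_mA`, then 1044 feature columns.
#' @export
feature_table <- function(trials) {
  key <- vapply(trials, function(tr) paste(tr$rat_id, tr$session_id,
                                           sep = "\x1f"), "")
  groups <- split(trials, key)
  rows <- lapply(groups, function(g) {
    arr <- session_array(g)
    feats <- flatten_session(arr)
    cbind(
      data.frame(rat_id = attr(arr, "rat_id"),
                 session_id = attr(arr, "session_id"),
                 session_type = attr(arr, "session_type"),
                 group = attr(arr, "group"), sex = attr(arr, "sex"),
                 intensity_mA = attr(arr, "intensity_mA"),
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(feats), optional = TRUE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$rat_id, out$session_id), ]
}

#' Metadata / feature split of a feature table
#'
#' @param features Data frame from [feature_table()] (or read back from
#'   CSV).
#' @return List with `X` (numeric matrix of features) and `meta` (data
#'   frame of metadata columns).
#' @export
split_features <- function(features) {
  meta_cols <- c("rat_id", "session_id", "session_type", "group", "sex",
                 "intensity_mA")
  missing_cols <- setdiff(meta_cols, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table is missing metadata column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(features[, setdiff(names(features), meta_cols)])
  storage.mode(X) <- "double"
  list(X = X, meta = features[, meta_cols])
}

#' Basic stacked ethogram plot
#'
#' Stacked-area plot of percent behavior per 200-ms bin with the canonical
#' category ordering; intended as a quick look, not a publication figure.
#'
#' @param percent 13 x 87 matrix from [group_ethogram()].
#' @param main Plot title.
#' @export
plot_ethogram <- function(percent, main = "Ethogram") {
  stopifnot(is.matrix(percent), ncol(percent) == frames_per_trial())
  times <- (seq_len(frames_per_trial()) - 26) * 0.2
  cum <- apply(percent, 2, cumsum)
  cols <- grDevices::hcl.colors(nrow(percent), "Spectral")
  graphics::plot(range(times), c(0, 100), type = "n", xlab = "time from cue onset (s)",
                 ylab = "% behavior", main = main)
  lower <- rep(0, ncol(percent))
  for (i in seq_len(nrow(percent))) {
    graphics::polygon(c(times, rev(times)), c(cum[i, ], rev(lower)),
                      col = cols[i], border = NA)
    lower <- cum[i, ]
  }
  graphics::abline(v = c(0, 10), lty = 2)
  graphics::legend("topright", legend = rownames(percent), fill = cols,
                   cex = 0.5, bg = "white")
  invisible(NULL)
}
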