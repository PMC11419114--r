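#' Nose-poke rate over a time window
#'
#' Counts poke events in the half-open window `[start, end)` and converts
#' to pokes per minute. The study's conventions: the 20-s pre-cue baseline
#' count is multiplied by 3, the 10-s cue count by 6; the factor must be
#' consistent with the window length (factor = 60 / window length).
#'
#' @param log An [event_log()].
#' @param start,end Window bounds in seconds, `start < end`.
#' @param scale_to_per_min Multiplier converting the count to pokes/min;
#'   defaults to `60 / (end - start)`.
#' @return Poke rate in pokes per minute.
#' @export
poke_rate <- function(log, start, end, scale_to_per_min = 60 / (end - start)) {
  stopifnot(inherits(log, "event_log"))
  if (!is.finite(start) || !is.finite(end) || end <= start) {
    stop("window must satisfy start < end", call. = FALSE)
  }
  if (abs(scale_to_per_min - 60 / (end - start)) > 1e-9) {
    stop("scale_to_per_min (", scale_to_per_min,
         ") inconsistent with window length ", end - start, " s",
         call. = FALSE)
  }
  pokes <- log$time_s[log$event == "poke"]
  sum(pokes >= start & pokes < end) * scale_to_per_min
}

#' Conditioned suppression ratio
#'
#' `(baseline_rate - cue_rate) / (baseline_rate + cue_rate)`: 1 means
#' complete suppression of poking during the cue, 0 equivalent rates,
#' negative values elevated poking during the cue. A 0/0 trial (no pokes in
#' either window) is undefined and returned as `NA`; such trials are
#' excluded from session means.
#'
#' @param baseline_rate,cue_rate Non-negative poke rates (pokes/min);
#'   vectorized.
#' @return Numeric ratio in `[-1, 1]`, or `NA` where both rates are zero.
#' @export
suppression_ratio <- function(baseline_rate, cue_rate) {
  if (any(baseline_rate < 0, na.rm = TRUE) || any(cue_rate < 0, na.rm = TRUE)) {
    stop("poke rates must be non-negative", call. = FALSE)
  }
  denom <- baseline_rate + cue_rate
  ifelse(denom > 0, (baseline_rate - cue_rate) / denom, NA_real_)
}

#' Per-trial suppression ratios for a session
#'
#' For each cue interval in the log, computes the baseline rate over the
#' 20 s immediately pre-cue (x3) and the cue rate over the cue interval
#' (x6 for the nominal 10-s cue), then the suppression ratio. The session
#' mean is taken over defined ratios only.
#'
#' @param log An [event_log()] with at least one cue interval.
#' @param baseline_s Baseline window length in seconds (default 20).
#' @return List with `records` (data frame: `trial_index`,
#'   `baseline_rate`, `cue_rate`, `ratio`) and `mean_ratio` (`NA` if no
#'   trial has a defined ratio).
#' @export
session_suppression <- function(log, baseline_s = 20) {
  cues <- cue_intervals(log)
  if (nrow(cues) == 0) {
    stop("event log contains no cue interval", call. = FALSE)
  }
  windows_start <- cues$onset - baseline_s
  if (any(windows_start < 0)) {
    stop("baseline window extends before session start", call. = FALSE)
  }
  if (nrow(cues) > 1 &&
      any(windows_start[-1] < cues$offset[-nrow(cues)])) {
    stop("baseline window overlaps the previous trial's cue period",
         call. = FALSE)
  }
  records <- do.call(rbind, lapply(seq_len(nrow(cues)), function(i) {
    b <- poke_rate(log, windows_start[i], cues$onset[i])
    cu <- poke_rate(log, cues$onset[i], cues$offset[i])
    data.frame(trial_index = i, baseline_rate = b, cue_rate = cu,
               ratio = suppression_ratio(b, cu))
  }))
  defined <- records$ratio[!is.na(records$ratio)]
  list(
    records = records,
    mean_ratio = if (length(defined) > 0) mean(defined) else NA_real_
  )
}

#' Suppression table across many sessions
#'
#' Convenience wrapper running [session_suppression()] on each event log
#' and binding results with session metadata.
#'
#' @param logs List of [event_log()] objects (with metadata attributes, as
#'   produced by [simulate_experiment()]).
#' @return Data frame with one row per trial: `rat_id`, `session_id`,
#'   `session_type`, `trial_index`, `baseline_rate`, `cue_rate`, `ratio`.
#' @export
suppression_table <- function(logs) {
  do.call(rbind, lapply(logs, function(log) {
    rec <- session_suppression(log)$records
    cbind(
      data.frame(rat_id = attr(log, "rat_id"),
                 session_id = attr(log, "session_id"),
                 session_type = attr(log, "session_type"),
                 stringsAsFactors = FALSE),
      rec
    )
  }))
}
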