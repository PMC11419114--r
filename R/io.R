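#' Construct an operant event log
#'
#' Timestamped nose-poke, cue and shock events for one session. Events are
#' sorted stably by time (file/input order breaks ties); cue_on/cue_off
#' events must strictly alternate, starting with cue_on.
#'
#' @param time_s Numeric, non-negative event times in seconds.
#' @param event Character, each one of `"poke"`, `"cue_on"`, `"cue_off"`,
#'   `"shock"`.
#' @param rat_id,session_id,session_type Optional session metadata.
#' @return An object of class `event_log`: a data frame with columns
#'   `time_s` and `event`.
#' @export
event_log <- function(time_s, event, rat_id = NA_character_,
                      session_id = NA_character_,
                      session_type = NA_character_) {
  if (length(time_s) != length(event)) {
    stop("time_s and event must have equal length", call. = FALSE)
  }
  time_s <- as.numeric(time_s)
  event <- as.character(event)
  if (any(is.na(time_s)) || any(time_s < 0)) {
    stop("event times must be non-negative numbers", call. = FALSE)
  }
  bad <- setdiff(unique(event), c("poke", "cue_on", "cue_off", "shock"))
  if (length(bad) > 0) {
    stop("unknown event kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(time_s)  # stable: ties keep input order
  df <- data.frame(time_s = time_s[ord], event = event[ord],
                   stringsAsFactors = FALSE)
  cues <- df$event[df$event %in% c("cue_on", "cue_off")]
  if (length(cues) > 0) {
    expected <- rep(c("cue_on", "cue_off"), length.out = length(cues))
    if (!identical(cues, expected) || length(cues) %% 2 != 0) {
      stop("cue_on/cue_off events must strictly alternate, starting with ",
           "cue_on and ending with cue_off", call. = FALSE)
    }
  }
  attr(df, "rat_id") <- as.character(rat_id)
  attr(df, "session_id") <- as.character(session_id)
  attr(df, "session_type") <- as.character(session_type)
  class(df) <- c("event_log", "data.frame")
  df
}

#' Cue intervals of an event log
#'
#' @param log An `event_log`.
#' @return Data frame with columns `onset` and `offset` (seconds), one row
#'   per cue presentation, in time order.
#' @export
cue_intervals <- function(log) {
  stopifnot(inherits(log, "event_log"))
  on <- log$time_s[log$event == "cue_on"]
  off <- log$time_s[log$event == "cue_off"]
  data.frame(onset = on, offset = off)
}

#' Read frame-level behavior labels
#'
#' Parses a frame-label CSV (header exactly
#' `rat_id,session_id,session_type,trial_index,frame_index,observer_id,label`)
#' into a list of [trial_frames()] objects, one per
#' (rat, session, trial, observer). Group/sex/intensity metadata, which do
#' not travel in the label file (scoring is blinded), can be attached from a
#' rat metadata table.
#'
#' @param path CSV file path.
#' @param metadata Optional data frame with columns `rat_id`, `group`,
#'   `sex`, `intensity_mA` (see [write_rat_metadata()]).
#' @return List of `trial_frames`.
#' @export
read_frame_labels <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  needed <- c("rat_id", "session_id", "session_type", "trial_index",
              "frame_index", "observer_id", "label")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("frame-label file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$trial_index <- as.integer(df$trial_index)
  df$frame_index <- as.integer(df$frame_index)
  bad_lab <- !df$label %in% behavior_labels()
  if (any(bad_lab)) {
    stop("unknown behavior label '", df$label[which(bad_lab)[1]],
         "' at row ", which(bad_lab)[1], " of ", path, call. = FALSE)
  }
  if (any(is.na(df$frame_index)) || any(df$frame_index < 1) ||
      any(df$frame_index > frames_per_trial())) {
    stop("frame_index must be an integer in 1..", frames_per_trial(),
         call. = FALSE)
  }
  key <- interaction(df$rat_id, df$session_id, df$trial_index,
                     df$observer_id, drop = TRUE, lex.order = TRUE)
  out <- lapply(split(df, key), function(g) {
    dup <- duplicated(g$frame_index)
    if (any(dup)) {
      stop("duplicate frame_index ", g$frame_index[dup][1],
           " for rat ", g$rat_id[1], " session ", g$session_id[1],
           " trial ", g$trial_index[1], " observer ", g$observer_id[1],
           call. = FALSE)
    }
    gaps <- setdiff(seq_len(frames_per_trial()), g$frame_index)
    if (length(gaps) > 0) {
      stop("incomplete trial (rat ", g$rat_id[1], ", session ",
           g$session_id[1], ", trial ", g$trial_index[1], ", observer ",
           g$observer_id[1], "): missing frame(s) ",
           paste(gaps, collapse = ", "), call. = FALSE)
    }
    g <- g[order(g$frame_index), ]
    meta <- list(group = NA_character_, sex = NA_character_,
                 intensity_mA = NA_real_)
    if (!is.null(metadata)) {
      m <- metadata[metadata$rat_id == g$rat_id[1], , drop = FALSE]
      if (nrow(m) == 1) {
        meta <- list(group = m$group, sex = m$sex,
                     intensity_mA = as.numeric(m$intensity_mA))
      }
    }
    trial_frames(
      rat_id = g$rat_id[1], session_id = g$session_id[1],
      session_type = g$session_type[1], trial_index = g$trial_index[1],
      labels = g$label, group = meta$group, sex = meta$sex,
      intensity_mA = meta$intensity_mA, observer_id = g$observer_id[1]
    )
  })
  names(out) <- NULL
  out
}

#' Write frame-level behavior labels
#'
#' Inverse of [read_frame_labels()]; emits the canonical 7-column dialect.
#'
#' @param trials List of `trial_frames`.
#' @param path Output CSV path.
#' @export
write_frame_labels <- function(trials, path) {
  rows <- lapply(trials, function(tr) {
    data.frame(
      rat_id = tr$rat_id, session_id = tr$session_id,
      session_type = tr$session_type, trial_index = tr$trial_index,
      frame_index = seq_len(frames_per_trial()),
      observer_id = tr$observer_id, label = tr$labels,
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write the rat metadata table
#'
#' Group, sex and shock intensity per rat travel separately from the
#' blinded frame-label files.
#'
#' @param path CSV path with columns `rat_id,group,sex,intensity_mA`.
#' @return Data frame.
#' @export
read_rat_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("rat_id", "group", "sex", "intensity_mA")
  if (!all(needed %in% names(df))) {
    stop("rat metadata file needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  df$rat_id <- as.character(df$rat_id)
  df
}

#' @rdname read_rat_metadata
#' @param metadata Data frame as returned by [read_rat_metadata()].
#' @export
write_rat_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an operant event log
#'
#' @param path CSV path with header `time_s,event`.
#' @inheritParams event_log
#' @return An `event_log`.
#' @export
read_event_log <- function(path, rat_id = NA_character_,
                           session_id = NA_character_,
                           session_type = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "event") %in% names(df))) {
    stop("event-log file needs columns time_s,event", call. = FALSE)
  }
  event_log(df$time_s, df$event, rat_id = rat_id, session_id = session_id,
            session_type = session_type)
}

#' Write an operant event log
#'
#' @param log An `event_log`.
#' @param path Output CSV path.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  utils::write.csv(data.frame(time_s = log$time_s, event = log$event),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
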