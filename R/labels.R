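#' Behavior label alphabet
#'
#' The canonical, closed set of frame labels: twelve mutually exclusive
#' scored behaviors plus `background` ("specific behavior cannot be
#' discerned"). The order returned here is the fixed label order used in
#' every matrix output of the package (ethograms, confusion matrices,
#' feature vectors).
#'
#' @return Character vector of length 13.
#' @export
behavior_labels <- function() {
  c("freeze", "stretch", "rear", "light_rear", "scale", "light_scale",
    "jump", "locomote", "backpedal", "cup", "port", "groom", "background")
}

#' Scored behaviors (background excluded)
#'
#' @return Character vector of length 12.
#' @export
scored_behaviors <- function() {
  setdiff(behavior_labels(), "background")
}

#' Multi-behavior categories
#'
#' Groupings used for feature-subset classification: Immobile (freeze,
#' stretch), Horizontal (locomote, backpedal), Vertical (rear, scale, jump
#' and their light-directed variants), Reward (cup, port). Grooming belongs
#' to no category.
#'
#' @return Named list of character vectors.
#' @export
behavior_categories <- function() {
  list(
    Immobile   = c("freeze", "stretch"),
    Horizontal = c("locomote", "backpedal"),
    Vertical   = c("rear", "scale", "jump", "light_rear", "light_scale"),
    Reward     = c("cup", "port")
  )
}

#' Trial period frame ranges
#'
#' Frames are 1-based and inclusive: baseline 1-25 (5 s pre-cue), cue 26-75
#' (10 s light), post 76-87 (2.5 s after light offset), at 5 frames/s.
#' Frame 26 begins at cue onset (t = 0 s); each frame spans 200 ms.
#'
#' @param period One of `"baseline"`, `"cue"`, `"post"`, `"all"`.
#' @return Integer vector of frame indices.
#' @export
period_frames <- function(period = c("baseline", "cue", "post", "all")) {
  period <- match.arg(period)
  switch(period,
    baseline = 1:25,
    cue      = 26:75,
    post     = 76:87,
    all      = 1:87
  )
}

#' Number of frames per trial
#' @export
frames_per_trial <- function() 87L

assert_labels <- function(labels) {
  if (length(labels) != frames_per_trial()) {
    stop("a trial must have exactly ", frames_per_trial(),
         " frame labels, got ", length(labels), call. = FALSE)
  }
  bad <- setdiff(unique(labels), behavior_labels())
  if (length(bad) > 0) {
    stop("unknown behavior label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(labels)
}

#' Construct a single scored trial
#'
#' The atomic unit of scored behavior: one trial's 87 ordered frame labels
#' (one label per 200-ms frame) plus identifying metadata.
#'
#' @param rat_id,session_id Character identifiers.
#' @param session_type `"conditioning"`, `"extinction"` or `"preexposure"`.
#' @param trial_index Integer >= 1.
#' @param labels Character vector of length 87, each from
#'   [behavior_labels()].
#' @param group `"paired"` or `"unpaired"`.
#' @param sex `"female"` or `"male"`.
#' @param intensity_mA Positive foot-shock intensity in mA.
#' @param observer_id Identifier of the scoring observer.
#' @return An object of class `trial_frames`.
#' @export
trial_frames <- function(rat_id, session_id, session_type, trial_index,
                         labels, group = NA_character_, sex = NA_character_,
                         intensity_mA = NA_real_, observer_id = "obs1") {
  session_type <- match.arg(session_type,
                            c("conditioning", "extinction", "preexposure"))
  trial_index <- as.integer(trial_index)
  if (is.na(trial_index) || trial_index < 1L) {
    stop("trial_index must be a positive integer", call. = FALSE)
  }
  if (!is.na(group)) group <- match.arg(group, c("paired", "unpaired"))
  if (!is.na(sex)) sex <- match.arg(sex, c("female", "male"))
  if (!is.na(intensity_mA) && intensity_mA <= 0) {
    stop("intensity_mA must be positive", call. = FALSE)
  }
  assert_labels(labels)
  structure(
    list(
      rat_id = as.character(rat_id),
      session_id = as.character(session_id),
      session_type = session_type,
      trial_index = trial_index,
      group = group,
      sex = sex,
      intensity_mA = intensity_mA,
      observer_id = as.character(observer_id),
      labels = as.character(labels),
      frame_period_s = 0.2
    ),
    class = "trial_frames"
  )
}

#' @export
print.trial_frames <- function(x, ...) {
  cat(sprintf("<trial_frames> rat %s, session %s (%s), trial %d, observer %s\n",
              x$rat_id, x$session_id, x$session_type, x$trial_index,
              x$observer_id))
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}
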