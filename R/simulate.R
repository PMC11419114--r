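# Synthetic behavior and nose-poke generator.
#
# Frame labels are drawn from a semi-Markov process: a behavior is held for
# a geometric dwell (explicit mean per behavior, so freeze bouts can honor
# the >= 3-frame scoring definition), then the next behavior is drawn from
# the active period's transition matrix. Kinetics switch at cue onset
# (frame 26) and at cue offset (frame 76), where the state is re-anchored
# by a draw from the incoming period's initial distribution - the synthetic
# analogue of cue- and shock-evoked behavioral transitions. Nose pokes are
# a piecewise-homogeneous Poisson process, suppressed during cue intervals.

.sub_seed <- function(...) {
  .eth_hash("sim", ...) %% 2147483646 + 1
}

#' Construct semi-Markov behavior kinetics
#'
#' Either from an explicit row-stochastic 13 x 13 transition matrix, or
#' from a target occupancy distribution (rows become the occupancy with the
#' current behavior removed and renormalized, and the initial distribution
#' is the occupancy itself).
#'
#' @param occupancy Named numeric simplex over [behavior_labels()]
#'   (ignored if `transition` is supplied).
#' @param dwell Named mean dwell times in frames (>= 1), one per label;
#'   a single number is recycled.
#' @param transition Optional explicit 13 x 13 row-stochastic matrix.
#' @param initial Optional initial distribution (defaults to `occupancy`,
#'   or the uniform distribution when `transition` is given).
#' @return Object of class `behavior_kinetics`: list with `transition`,
#'   `dwell`, `initial`.
#' @export
behavior_kinetics <- function(occupancy = NULL, dwell = 3,
                              transition = NULL, initial = NULL) {
  labs <- behavior_labels()
  k <- length(labs)
  if (is.null(transition)) {
    if (is.null(occupancy)) stop("need occupancy or transition", call. = FALSE)
    occ <- occupancy[labs]
    if (any(is.na(occ)) || any(occ < 0) || abs(sum(occ) - 1) > 1e-9) {
      stop("occupancy must be a non-negative simplex over all 13 labels",
           call. = FALSE)
    }
    transition <- matrix(0, k, k, dimnames = list(labs, labs))
    for (i in seq_len(k)) {
      row <- occ
      row[i] <- 0
      if (sum(row) == 0) row[i] <- 1 else row <- row / sum(row)
      transition[i, ] <- row
    }
    if (is.null(initial)) initial <- occ
  } else {
    transition <- as.matrix(transition)
    if (!identical(dim(transition), c(k, k))) {
      stop("transition must be 13 x 13", call. = FALSE)
    }
    if (any(transition < 0) ||
        any(abs(rowSums(transition) - 1) > 1e-12)) {
      stop("transition rows must be non-negative and sum to 1", call. = FALSE)
    }
    dimnames(transition) <- list(labs, labs)
    if (is.null(initial)) initial <- stats::setNames(rep(1 / k, k), labs)
  }
  if (is.null(names(initial))) names(initial) <- labs
  if (length(dwell) == 1) dwell <- stats::setNames(rep(dwell, k), labs)
  dwell <- dwell[labs]
  if (any(is.na(dwell)) || any(dwell < 1)) {
    stop("mean dwell must be >= 1 frame for every label", call. = FALSE)
  }
  initial <- initial[labs] / sum(initial[labs])
  structure(list(transition = transition, dwell = dwell, initial = initial),
            class = "behavior_kinetics")
}

.draw_dwell <- function(mean_dwell) {
  1L + stats::rgeom(1, 1 / mean_dwell)
}

.sim_segment <- function(kin, n, state = NULL, dwell_left = NULL) {
  labs <- behavior_labels()
  out <- character(n)
  if (is.null(state)) {
    state <- sample(labs, 1, prob = kin$initial)
    dwell_left <- .draw_dwell(kin$dwell[state])
  }
  for (f in seq_len(n)) {
    if (dwell_left <= 0) {
      state <- sample(labs, 1, prob = kin$transition[state, ])
      dwell_left <- .draw_dwell(kin$dwell[state])
    }
    out[f] <- state
    dwell_left <- dwell_left - 1
  }
  out
}

#' Simulate one trial's 87 frame labels
#'
#' @param kinetics List of three [behavior_kinetics()]: `baseline` (frames
#'   1-25), `cue` (26-75) and `late` (76-87: shock kinetics for paired
#'   conditioning trials, post-cue kinetics otherwise).
#' @param seed Optional integer for reproducibility.
#' @return Character vector of 87 labels.
#' @export
simulate_trial_labels <- function(kinetics, seed = NULL) {
  stopifnot(all(c("baseline", "cue", "late") %in% names(kinetics)))
  run <- function() {
    c(.sim_segment(kinetics$baseline, 25),
      .sim_segment(kinetics$cue, 50),
      .sim_segment(kinetics$late, 12))
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Simulate a long stationary behavior chain
#'
#' Runs a single period's kinetics for `n_frames` frames; useful for
#' checking occupancy against the kernel's stationary distribution.
#'
#' @param kinetics A [behavior_kinetics()].
#' @param n_frames Number of frames.
#' @param seed Optional integer.
#' @return Character label vector of length `n_frames`.
#' @export
simulate_chain <- function(kinetics, n_frames, seed = NULL) {
  if (is.null(seed)) .sim_segment(kinetics, n_frames)
  else .with_seed(seed, .sim_segment(kinetics, n_frames))
}

# Target occupancy distributions per group x period (proportion of frames
# in each behavior). Values emulate the qualitative ethogram structure of
# the study design: shared reward-seeking/exploration baseline; paired cue
# freeze + locomotion with reward and rearing suppression; unpaired cue
# light-directed rearing/scaling elevation; paired shock-evoked
# locomote/jump/backpedal burst; the paired post-cue (extinction) pattern
# resembles the shock response.
.default_occupancy <- function() {
  labs <- behavior_labels()
  mk <- function(...) {
    v <- stats::setNames(rep(0, length(labs)), labs)
    args <- c(...)
    v[names(args)] <- args
    v["background"] <- 1 - sum(v)
    stopifnot(v["background"] >= 0)
    v
  }
  list(
    base = mk(freeze = 0.01, stretch = 0.01, rear = 0.16, light_rear = 0.04,
              scale = 0.04, light_scale = 0.01, jump = 0.005,
              locomote = 0.06, backpedal = 0.005, cup = 0.22, port = 0.18,
              groom = 0.05),
    paired_cue = mk(freeze = 0.15, stretch = 0.03, rear = 0.06,
                    light_rear = 0.05, scale = 0.02, light_scale = 0.01,
                    jump = 0.01, locomote = 0.20, backpedal = 0.02,
                    cup = 0.08, port = 0.07, groom = 0.02),
    unpaired_cue = mk(freeze = 0.01, stretch = 0.01, rear = 0.17,
                      light_rear = 0.18, scale = 0.08, light_scale = 0.10,
                      jump = 0.01, locomote = 0.06, backpedal = 0.005,
                      cup = 0.12, port = 0.10, groom = 0.02),
    paired_shock = mk(freeze = 0.05, stretch = 0.02, rear = 0.02,
                      light_rear = 0.01, scale = 0.01, light_scale = 0.005,
                      jump = 0.15, locomote = 0.30, backpedal = 0.15,
                      cup = 0.03, port = 0.03, groom = 0.005),
    paired_post = mk(freeze = 0.08, stretch = 0.02, rear = 0.05,
                     light_rear = 0.03, scale = 0.01, light_scale = 0.005,
                     jump = 0.03, locomote = 0.25, backpedal = 0.05,
                     cup = 0.08, port = 0.08, groom = 0.02),
    unpaired_post = mk(freeze = 0.01, stretch = 0.01, rear = 0.15,
                       light_rear = 0.16, scale = 0.09, light_scale = 0.08,
                       jump = 0.01, locomote = 0.05, backpedal = 0.005,
                       cup = 0.12, port = 0.10, groom = 0.02)
  )
}

.default_dwell <- function() {
  c(freeze = 4, stretch = 3, rear = 4, light_rear = 4, scale = 4,
    light_scale = 4, jump = 2, locomote = 3, backpedal = 2, cup = 5,
    port = 5, groom = 5, background = 3)
}

.effect_weight <- function(effect_size) {
  switch(match.arg(effect_size, c("none", "moderate", "strong")),
         none = 0, moderate = 0.5, strong = 1)
}

#' Default period kinetics for one rat
#'
#' Resolves group, session type and effect size into the three period
#' kinetics used by [simulate_trial_labels()]. The effect size scales the
#' divergence of the group-specific cue/late occupancy from the shared
#' baseline occupancy: `none` makes paired and unpaired kinetics
#' identical, `strong` uses the full group-specific targets. Optional
#' per-rat multipliers model individual behavioral style.
#'
#' @param group `"paired"` or `"unpaired"`.
#' @param session_type `"conditioning"` or `"extinction"`.
#' @param effect_size `"none"`, `"moderate"` or `"strong"`.
#' @param rat_multipliers Optional named positive multipliers (one per
#'   label) applied to every period occupancy, then renormalized.
#' @return Named list of [behavior_kinetics()]: `baseline`, `cue`, `late`.
#' @export
default_kinetics <- function(group, session_type,
                             effect_size = "moderate",
                             rat_multipliers = NULL) {
  group <- match.arg(group, c("paired", "unpaired"))
  session_type <- match.arg(session_type, c("conditioning", "extinction"))
  e <- .effect_weight(effect_size)
  occ <- .default_occupancy()
  blend <- function(target) {
    v <- (1 - e) * occ$base + e * target
    if (!is.null(rat_multipliers)) v <- v * rat_multipliers[names(v)]
    v / sum(v)
  }
  cue_target <- if (group == "paired") occ$paired_cue else occ$unpaired_cue
  late_target <- if (group == "paired") {
    if (session_type == "conditioning") occ$paired_shock else occ$paired_post
  } else {
    occ$unpaired_post
  }
  base_occ <- occ$base
  if (!is.null(rat_multipliers)) {
    base_occ <- base_occ * rat_multipliers[names(base_occ)]
    base_occ <- base_occ / sum(base_occ)
  }
  dw <- .default_dwell()
  list(
    baseline = behavior_kinetics(occupancy = base_occ, dwell = dw),
    cue = behavior_kinetics(occupancy = blend(cue_target), dwell = dw),
    late = behavior_kinetics(occupancy = blend(late_target), dwell = dw)
  )
}

#' Simulation configuration
#'
#' Defaults reproduce the study design cardinalities: 16 rats per group
#' (sex-balanced, two shock intensities), 2 scored sessions x 4 trials x
#' 87 frames = 22,272 frames and 64 session arrays.
#'
#' @param n_rats_per_group Rats per group (default 16).
#' @param intensities Two shock intensities in mA (default 0.5, 0.35).
#' @param trials_per_session Trials per session (default 4).
#' @param sessions Scored session types.
#' @param effect_size `"none"`, `"moderate"` or `"strong"`.
#' @param lambda_baseline Baseline nose-poke rate, pokes/min (default 20).
#' @param poke_suppression Named cue-period rate suppression in `[0, 1]`
#'   for each group.
#' @param rat_noise_shape Gamma shape of per-rat occupancy multipliers
#'   (larger = more homogeneous rats; default 6).
#' @param observer_flip Probability a scored frame is indiscernible and
#'   labeled background (default 0.06).
#' @param n_observers Number of scoring observers (default 6).
#' @param seed Root seed; all per-rat/per-trial substreams derive from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_rats_per_group = 16, intensities = c(0.5, 0.35),
                       trials_per_session = 4,
                       sessions = c("conditioning", "extinction"),
                       effect_size = "moderate", lambda_baseline = 20,
                       poke_suppression = c(paired = 0.85, unpaired = 0.15),
                       rat_noise_shape = 6, observer_flip = 0.06,
                       n_observers = 6, seed = 1) {
  effect_size <- match.arg(effect_size, c("none", "moderate", "strong"))
  stopifnot(n_rats_per_group >= 2, length(intensities) == 2,
            all(poke_suppression >= 0), all(poke_suppression <= 1),
            observer_flip >= 0, observer_flip < 1)
  structure(
    list(n_rats_per_group = n_rats_per_group, intensities = intensities,
         trials_per_session = trials_per_session, sessions = sessions,
         effect_size = effect_size, lambda_baseline = lambda_baseline,
         poke_suppression = poke_suppression,
         rat_noise_shape = rat_noise_shape, observer_flip = observer_flip,
         n_observers = n_observers, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a nose-poke event log
#'
#' Homogeneous Poisson poking at `lambda_baseline` pokes/min outside cue
#' intervals and `lambda_baseline * (1 - suppression)` inside them.
#'
#' @param lambda_baseline Baseline rate, pokes/min (>= 0).
#' @param suppression Cue-period rate suppression in `[0, 1]`.
#' @param cue_onsets Cue onset times (s).
#' @param cue_duration Cue duration (s), default 10.
#' @param duration Session duration (s).
#' @param shock_times Optional shock event times (s).
#' @param seed Optional integer.
#' @inheritParams event_log
#' @return An [event_log()] containing pokes, cue_on/cue_off pairs and any
#'   shocks.
#' @export
simulate_pokes <- function(lambda_baseline, suppression, cue_onsets,
                           cue_duration = 10, duration,
                           shock_times = numeric(0), seed = NULL,
                           rat_id = NA_character_,
                           session_id = NA_character_,
                           session_type = NA_character_) {
  if (lambda_baseline < 0) stop("rate must be >= 0", call. = FALSE)
  if (suppression < 0 || suppression > 1) {
    stop("suppression must be in [0, 1]", call. = FALSE)
  }
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  bounds <- sort(unique(c(0, cue_onsets, cue_onsets + cue_duration,
                          duration)))
  bounds <- bounds[bounds >= 0 & bounds <= duration]
  run <- function() {
    pokes <- numeric(0)
    for (i in seq_len(length(bounds) - 1)) {
      a <- bounds[i]; b <- bounds[i + 1]
      in_cue <- any(a >= cue_onsets & a < cue_onsets + cue_duration)
      rate <- lambda_baseline / 60 * if (in_cue) 1 - suppression else 1
      n <- stats::rpois(1, rate * (b - a))
      if (n > 0) pokes <- c(pokes, sort(stats::runif(n, a, b)))
    }
    pokes
  }
  pokes <- if (is.null(seed)) run() else .with_seed(seed, run())
  times <- c(pokes, cue_onsets, cue_onsets + cue_duration, shock_times)
  kinds <- c(rep("poke", length(pokes)), rep("cue_on", length(cue_onsets)),
             rep("cue_off", length(cue_onsets)),
             rep("shock", length(shock_times)))
  event_log(times, kinds, rat_id = rat_id, session_id = session_id,
            session_type = session_type)
}

#' Simulate the full experiment
#'
#' Generates the complete factorial dataset: frame labels for every rat x
#' session x trial (semi-Markov behavior with per-rat heterogeneity and
#' observer background-flip noise, trials assigned to distinct observers
#' within a session) plus one nose-poke event log per rat-session, with a
#' rat metadata table. Fully reproducible from the config seed via
#' hierarchical substreams.
#'
#' @param config A [sim_config()].
#' @return List with `trials` (list of [trial_frames()]), `events` (list
#'   of [event_log()]), `metadata` (rat table), `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  labs <- behavior_labels()
  n_per <- config$n_rats_per_group
  n_rats <- 2 * n_per
  groups <- rep(c("paired", "unpaired"), each = n_per)
  sexes <- rep(rep(c("female", "male"), each = n_per / 2), 2)
  # intensities balanced within group x sex
  intens <- unlist(lapply(seq_len(n_rats), function(i) {
    config$intensities[(i - 1) %% 2 + 1]
  }))
  metadata <- data.frame(
    rat_id = sprintf("r%02d", seq_len(n_rats)),
    group = groups, sex = sexes, intensity_mA = intens,
    stringsAsFactors = FALSE
  )
  cue_onsets <- c(300, 800, 1300, 1800)
  session_ids <- stats::setNames(
    sprintf("S%d", seq_along(config$sessions)), config$sessions)
  trials <- list()
  events <- list()
  observers <- sprintf("obs%d", seq_len(config$n_observers))
  for (i in seq_len(n_rats)) {
    rat <- metadata$rat_id[i]
    mult <- .with_seed(.sub_seed(config$seed, "rat", i), {
      m <- stats::rgamma(length(labs), shape = config$rat_noise_shape,
                         rate = config$rat_noise_shape)
      stats::setNames(pmax(m, 0.05), labs)
    })
    for (st in config$sessions) {
      kin <- default_kinetics(metadata$group[i], st,
                              effect_size = config$effect_size,
                              rat_multipliers = mult)
      obs_assign <- .with_seed(
        .sub_seed(config$seed, "obs", i, st),
        sample(observers, config$trials_per_session)
      )
      for (tr in seq_len(config$trials_per_session)) {
        tseed <- .sub_seed(config$seed, "trial", i, st, tr)
        lab_seq <- simulate_trial_labels(kin, seed = tseed)
        if (config$observer_flip > 0) {
          lab_seq <- .with_seed(.sub_seed(config$seed, "flip", i, st, tr), {
            flip <- stats::runif(length(lab_seq)) < config$observer_flip
            lab_seq[flip] <- "background"
            lab_seq
          })
        }
        trials[[length(trials) + 1]] <- trial_frames(
          rat_id = rat, session_id = session_ids[[st]], session_type = st,
          trial_index = tr, labels = lab_seq, group = metadata$group[i],
          sex = metadata$sex[i], intensity_mA = metadata$intensity_mA[i],
          observer_id = obs_assign[tr]
        )
      }
      shock_times <- if (st == "conditioning") {
        if (metadata$group[i] == "paired") cue_onsets + 10
        else cue_onsets + 250  # unpaired: shocks midway between cues
      } else numeric(0)
      events[[length(events) + 1]] <- simulate_pokes(
        lambda_baseline = config$lambda_baseline,
        suppression = config$poke_suppression[[metadata$group[i]]],
        cue_onsets = cue_onsets, cue_duration = 10, duration = 2580,
        shock_times = shock_times,
        seed = .sub_seed(config$seed, "pokes", i, st),
        rat_id = rat, session_id = session_ids[[st]], session_type = st
      )
    }
  }
  list(trials = trials, events = events, metadata = metadata,
       config = config)
}

#' Simulate multi-observer comparison trials
#'
#' Generates trials in which every observer scores the same latent behavior
#' sequence, with observer-specific noise: with probability `flip_prob` a
#' frame is scored background (the dominant real-world disagreement mode),
#' and with probability `confuse_prob` it is scored as a random other
#' behavior. Eight trials scored by six observers yields the study's
#' 696-comparison-frame design (8 x 87).
#'
#' @param n_trials Number of comparison trials (default 8).
#' @param n_observers Number of observers (default 6).
#' @param flip_prob Background-flip probability (default 0.12).
#' @param confuse_prob Behavior-confusion probability (default 0.03).
#' @param effect_size Passed to [default_kinetics()].
#' @param seed Integer seed.
#' @return List of `trial_frames` (`n_trials * n_observers` entries).
#' @export
simulate_comparison_trials <- function(n_trials = 8, n_observers = 6,
                                       flip_prob = 0.12,
                                       confuse_prob = 0.03,
                                       effect_size = "moderate", seed = 1) {
  labs <- behavior_labels()
  out <- list()
  for (tr in seq_len(n_trials)) {
    grp <- if (tr %% 2 == 1) "paired" else "unpaired"
    kin <- default_kinetics(grp, "conditioning", effect_size = effect_size)
    truth <- simulate_trial_labels(kin, seed = .sub_seed(seed, "cmp", tr))
    for (ob in seq_len(n_observers)) {
      noisy <- .with_seed(.sub_seed(seed, "cmpobs", tr, ob), {
        v <- truth
        u <- stats::runif(length(v))
        v[u < flip_prob] <- "background"
        confuse <- u >= flip_prob & u < flip_prob + confuse_prob
        if (any(confuse)) {
          v[confuse] <- vapply(v[confuse], function(cur) {
            sample(setdiff(labs, cur), 1)
          }, "")
        }
        v
      })
      out[[length(out) + 1]] <- trial_frames(
        rat_id = "cmp", session_id = "CMP", session_type = "conditioning",
        trial_index = tr, labels = noisy, group = grp,
        observer_id = sprintf("obs%d", ob)
      )
    }
  }
  out
}
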