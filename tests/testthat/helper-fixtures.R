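# Shared fixture builders; everything is generated in code.

make_trial <- function(labels = rep("background", 87), rat = "r01",
                       session = "S1", type = "conditioning", trial = 1L,
                       group = NA_character_, sex = NA_character_,
                       intensity = NA_real_, observer = "obs1") {
  trial_frames(rat_id = rat, session_id = session, session_type = type,
               trial_index = trial, labels = labels, group = group,
               sex = sex, intensity_mA = intensity, observer_id = observer)
}

# a rat-session of 4 trials with given label sequences
make_session <- function(label_list, rat = "r01", session = "S1",
                         type = "conditioning", group = "paired",
                         sex = "female", intensity = 0.5) {
  lapply(seq_along(label_list), function(i) {
    make_trial(label_list[[i]], rat = rat, session = session, type = type,
               trial = i, group = group, sex = sex, intensity = intensity)
  })
}

# hand-rolled pooled-variance two-sample t (independent oracle)
oracle_pooled_t <- function(x, y) {
  df <- length(x) + length(y) - 2
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) / df
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  list(t = tval, p = 2 * pt(-abs(tval), df))
}

# session-level cache so each test file generates the default experiment
# at most once
.fixture_cache <- new.env(parent = emptyenv())
cached_default_experiment <- function(seed = 1, effect_size = "moderate") {
  key <- paste0("exp_", seed, "_", effect_size)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_experiment(
      sim_config(seed = seed, effect_size = effect_size))
  }
  .fixture_cache[[key]]
}
cached_default_features <- function(seed = 1, effect_size = "moderate") {
  key <- paste0("ft_", seed, "_", effect_size)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- feature_table(
      cached_default_experiment(seed, effect_size)$trials)
  }
  .fixture_cache[[key]]
}
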