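# Shared fixture builders. Everything is generated in code at test time.

# one-row trial table with fully resolved events, for kernel-level tests
single_trial <- function(cue_on = 1000, rt = 300, modality = "V",
                         choice = "right") {
  structure(data.frame(
    trial_id = 1L, session_id = "fix", stimulus_side = choice,
    modality = modality, poke_in_ms = cue_on - 500, cue_on_ms = cue_on,
    withdrawal_ms = cue_on + rt, choice_side = choice, correct = TRUE,
    rt_ms = rt, movement_time_ms = 300, is_correction_trial = FALSE,
    injection_condition = "none", stringsAsFactors = FALSE
  ), class = c("trial_table", "data.frame"))
}

as_unit <- function(times, unit_id = 1L, ground_truth = NULL) {
  structure(list(unit_id = unit_id, spike_times_ms = sort(times),
                 ground_truth = ground_truth),
            class = "unit_spikes")
}

# session trimmed to fixed neural-filtered trial counts; thin alias of the
# package-level builder the experiments use
neural_session <- function(n_per_dir, seed, per_modality = FALSE) {
  neural_session_trials(n_per_dir, seed, per_modality = per_modality)
}

# brute-force ROC area: explicit pair counting, ties worth one half
brute_roc_area <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) {
    wins <- wins + (x > y) + 0.5 * (x == y)
  }
  wins / (length(a) * length(b))
}

# refractory-respecting Poisson spike train (ms), used for detection tests
poisson_train_ms <- function(rate_hz, duration_ms, refractory_ms = 3,
                             margin_ms = 5) {
  n_draw <- ceiling(rate_hz * duration_ms / 1000 * 1.5) + 20
  isi <- stats::rexp(n_draw, rate_hz) * 1000 + refractory_ms
  st <- cumsum(isi)
  st[st < duration_ms - margin_ms & st > margin_ms]
}
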