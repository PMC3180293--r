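#' Parameters of one synthetic neuron
#'
#' The generative model ties together every quantity the analysis side
#' measures: a baseline rate, Gaussian sensory-evoked bumps per modality, and
#' a linear premovement ramp ending at nose withdrawal whose amplitude is
#' direction-gained, RT-coupled and (under AV) scaled by a multisensory
#' modulation factor.
#'
#' @param unit_id integer id.
#' @param baseline_rate_sp_s baseline firing rate, sp/s (>= 0).
#' @param premove_amp_sp_s signed ramp amplitude at withdrawal; positive =
#'   premovement activation, negative = suppression.
#' @param premove_onset_ms ramp onset relative to withdrawal (negative).
#' @param rt_coupling_beta signed gain (sp/s per ms) linking the trial's RT
#'   deviation from the session median to the ramp amplitude; its sign sets
#'   the sign of the measured RT--rate correlation.
#' @param direction_gain_contra,direction_gain_ipsi nonnegative multipliers on
#'   the ramp amplitude for contraversive / ipsiversive movements.
#' @param sensory_amp_V_sp_s,sensory_amp_A_sp_s evoked bump amplitudes.
#' @param sensory_latency_ms,sensory_width_ms bump peak latency after cue
#'   onset and Gaussian width.
#' @param av_sensory_gain multiplier applied to both evoked bumps under AV.
#' @param av_modulation_factor multiplier on the premovement ramp under AV;
#'   > 1 enhancement, < 1 depression.
#' @param generated_type_label ground-truth label in
#'   `c("1","2","3","4","none")`.
#' @return object of class `neuron_params`.
#' @export
neuron_params <- function(unit_id = 1L,
                          baseline_rate_sp_s = 10,
                          premove_amp_sp_s = 8,
                          premove_onset_ms = -150,
                          rt_coupling_beta = 0,
                          direction_gain_contra = 1,
                          direction_gain_ipsi = 1,
                          sensory_amp_V_sp_s = 0,
                          sensory_amp_A_sp_s = 0,
                          sensory_latency_ms = 40,
                          sensory_width_ms = 15,
                          av_sensory_gain = 1,
                          av_modulation_factor = 1,
                          generated_type_label = "none") {
  stopifnot(
    baseline_rate_sp_s >= 0, premove_onset_ms < 0,
    direction_gain_contra >= 0, direction_gain_ipsi >= 0,
    sensory_width_ms > 0,
    generated_type_label %in% c("1", "2", "3", "4", "none")
  )
  structure(list(
    unit_id = as.integer(unit_id),
    baseline_rate_sp_s = baseline_rate_sp_s,
    premove_amp_sp_s = premove_amp_sp_s,
    premove_onset_ms = premove_onset_ms,
    rt_coupling_beta = rt_coupling_beta,
    direction_gain_contra = direction_gain_contra,
    direction_gain_ipsi = direction_gain_ipsi,
    sensory_amp_V_sp_s = sensory_amp_V_sp_s,
    sensory_amp_A_sp_s = sensory_amp_A_sp_s,
    sensory_latency_ms = sensory_latency_ms,
    sensory_width_ms = sensory_width_ms,
    av_sensory_gain = av_sensory_gain,
    av_modulation_factor = av_modulation_factor,
    generated_type_label = generated_type_label
  ), class = "neuron_params")
}

#' Map choice sides to movement directions relative to the recorded hemisphere
#'
#' A left-hemisphere recording makes rightward choices contraversive.
#'
#' @param choice_side character vector in `c("left","right","none")`.
#' @param hemisphere `"left"` (default) or `"right"`.
#' @return character vector in `c("contra","ipsi","none")`.
#' @export
movement_direction <- function(choice_side, hemisphere = "left") {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  contra_side <- if (hemisphere == "left") "right" else "left"
  ifelse(choice_side == "none", "none",
         ifelse(choice_side == contra_side, "contra", "ipsi"))
}

# signed premovement ramp amplitude for one trial (before clamping)
ramp_amplitude <- function(trial, params, median_rt, hemisphere = "left") {
  dir <- movement_direction(trial$choice_side, hemisphere)
  gain <- switch(dir,
                 contra = params$direction_gain_contra,
                 ipsi = params$direction_gain_ipsi,
                 none = 0)
  amp <- params$premove_amp_sp_s +
    params$rt_coupling_beta * (trial$rt_ms - median_rt)
  if (identical(trial$modality, "AV")) amp <- amp * params$av_modulation_factor
  gain * amp
}

#' Instantaneous firing-rate function of one trial
#'
#' Piecewise rate on the session clock: baseline, plus Gaussian sensory bumps
#' after cue onset (V and/or A amplitude; both present under AV, each scaled
#' by `av_sensory_gain`), plus a linear premovement ramp rising from
#' `premove_onset_ms` before withdrawal to its signed amplitude at withdrawal
#' and decaying back over 100 ms. The summed rate is clamped at zero. Catch
#' trials carry baseline only.
#'
#' @param trial one-row `trial_table`.
#' @param params a [neuron_params()].
#' @param median_rt session median RT (ms) used as the RT-coupling reference.
#' @param hemisphere recorded hemisphere, see [movement_direction()].
#' @return function mapping session-clock times (ms) to rates (sp/s).
#' @export
trial_rate_function <- function(trial, params, median_rt,
                                hemisphere = "left") {
  stopifnot(nrow(trial) == 1L)
  is_catch <- identical(trial$modality, "catch")
  cue_on <- trial$cue_on_ms
  wd <- trial$withdrawal_ms
  amp <- if (is_catch) 0 else ramp_amplitude(trial, params, median_rt, hemisphere)
  sens_amp <- 0
  if (!is_catch) {
    g <- if (identical(trial$modality, "AV")) params$av_sensory_gain else 1
    sens_amp <- c(
      V = g * params$sensory_amp_V_sp_s * (trial$modality %in% c("V", "AV")),
      A = g * params$sensory_amp_A_sp_s * (trial$modality %in% c("A", "AV"))
    )
  }
  onset <- params$premove_onset_ms

  function(t) {
    r <- rep(params$baseline_rate_sp_s, length(t))
    if (!is_catch && !is.na(cue_on)) {
      peak <- cue_on + params$sensory_latency_ms
      bump <- exp(-(t - peak)^2 / (2 * params$sensory_width_ms^2))
      r <- r + sum(sens_amp) * bump * (t >= cue_on)
    }
    if (!is_catch && !is.na(wd) && amp != 0) {
      rise <- t >= wd + onset & t < wd
      fall <- t >= wd & t < wd + 100
      r[rise] <- r[rise] + amp * (t[rise] - (wd + onset)) / (-onset)
      r[fall] <- r[fall] + amp * (1 - (t[fall] - wd) / 100)
    }
    pmax(r, 0)
  }
}

# analytic upper bound on the trial rate, valid because components add before
# the zero clamp and the clamp only lowers the rate
trial_rate_bound <- function(trial, params, median_rt, hemisphere = "left") {
  is_catch <- identical(trial$modality, "catch")
  b <- params$baseline_rate_sp_s
  if (is_catch) return(b)
  g <- if (identical(trial$modality, "AV")) params$av_sensory_gain else 1
  s <- g * (params$sensory_amp_V_sp_s * (trial$modality %in% c("V", "AV")) +
              params$sensory_amp_A_sp_s * (trial$modality %in% c("A", "AV")))
  amp <- ramp_amplitude(trial, params, median_rt, hemisphere)
  b + max(0, s) + max(0, amp)
}

#' Generate spike trains for a population by inhomogeneous-Poisson thinning
#'
#' For each unit and trial, homogeneous Poisson candidates at an analytic
#' upper bound of the trial rate are thinned by the ratio
#' `rate(t) / bound`, yielding an exact inhomogeneous Poisson train.
#' Spikes are generated in a window spanning each trial (500 ms before poke-in
#' to 400 ms after withdrawal, or the hold period for catch trials) and
#' concatenated on the session clock. Per-unit streams are derived from
#' `seed`, so a fixed seed reproduces every spike time exactly.
#'
#' @param trials a `trial_table`.
#' @param population list of [neuron_params()].
#' @param seed master seed.
#' @param hemisphere recorded hemisphere.
#' @return list of `unit_spikes` objects: `list(unit_id, spike_times_ms,
#'   ground_truth)` with strictly sorted nonnegative times.
#' @export
generate_spike_trains <- function(trials, population, seed = 1L,
                                  hemisphere = "left") {
  stopifnot(inherits(trials, "data.frame"))
  median_rt <- stats::median(trials$rt_ms, na.rm = TRUE)
  if (is.na(median_rt)) median_rt <- 0
  lapply(population, function(params) {
    st <- local_seed(derive_seed(seed, paste0("unit_", params$unit_id)), {
      times <- vector("list", nrow(trials))
      for (i in seq_len(nrow(trials))) {
        tr <- trials[i, , drop = FALSE]
        t0 <- tr$poke_in_ms - 500
        t1 <- if (is.na(tr$withdrawal_ms)) tr$poke_in_ms + 1200 else tr$withdrawal_ms + 400
        bound <- trial_rate_bound(tr, params, median_rt, hemisphere)
        if (bound <= 0 || t1 <= t0) next
        n_cand <- stats::rpois(1, bound * (t1 - t0) / 1000)
        if (n_cand == 0) next
        cand <- sort(stats::runif(n_cand, t0, t1))
        rate_fn <- trial_rate_function(tr, params, median_rt, hemisphere)
        keep <- stats::runif(n_cand) < rate_fn(cand) / bound
        times[[i]] <- cand[keep]
      }
      sort(unlist(times))
    })
    st <- st[st >= 0]
    structure(list(unit_id = params$unit_id,
                   spike_times_ms = st,
                   ground_truth = params),
              class = "unit_spikes")
  })
}

#' Build a typed synthetic population
#'
#' Convenience constructor for populations of the four movement-related
#' classes. Signs follow the class definitions: types 1/2 are premovement
#' activated, 3/4 suppressed; types 1/3 have positive RT--rate coupling, 2/4
#' negative.
#'
#' @param n_per_type units per class.
#' @param baseline_rate_sp_s,premove_amp_sp_s magnitudes shared by all units.
#' @param rt_coupling_beta magnitude of the RT coupling (sp/s per ms).
#' @param av_modulation_factor premovement AV factor applied to all units.
#' @param ... further arguments passed to [neuron_params()].
#' @return list of [neuron_params()] with ground-truth labels.
#' @export
typed_population <- function(n_per_type = 10L,
                             baseline_rate_sp_s = 10,
                             premove_amp_sp_s = 8,
                             rt_coupling_beta = 0.05,
                             av_modulation_factor = 1,
                             ...) {
  signs <- list(`1` = c(+1, +1), `2` = c(+1, -1),
                `3` = c(-1, +1), `4` = c(-1, -1))
  pop <- list()
  uid <- 0L
  for (type in names(signs)) {
    s <- signs[[type]]
    for (k in seq_len(n_per_type)) {
      uid <- uid + 1L
      pop[[uid]] <- neuron_params(
        unit_id = uid,
        baseline_rate_sp_s = baseline_rate_sp_s,
        premove_amp_sp_s = s[1] * premove_amp_sp_s,
        rt_coupling_beta = s[2] * rt_coupling_beta,
        av_modulation_factor = av_modulation_factor,
        generated_type_label = type,
        ...
      )
    }
  }
  pop
}
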