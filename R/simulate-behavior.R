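#' Task configuration for the synthetic session generator
#'
#' Defaults reproduce the published task structure: randomized 400--800 ms
#' foreperiod, 100-ms left/right cues drawn equiprobably from visual, auditory
#' and audiovisual modalities, 16.7% catch trials requiring a 1000-ms hold, a
#' 2.1-s response window, and per-modality reaction-time (RT) distributions
#' with audiovisual facilitation (means 386.3 / 394.9 / 322.4 ms for V / A /
#' AV). RTs are drawn from a shifted log-normal (shift 100 ms) matched to the
#' requested mean and SD.
#'
#' @param n_trials number of trials in the session.
#' @param foreperiod_range_ms numeric length-2, uniform foreperiod bounds.
#' @param cue_duration_ms stimulus duration.
#' @param catch_fraction probability a scheduled trial is a catch trial.
#' @param catch_hold_ms required hold duration on catch trials.
#' @param response_window_ms maximum allowed RT.
#' @param rt_mean_ms,rt_sd_ms named numeric vectors over `c("V","A","AV")`.
#' @param rt_shift_ms shift of the log-normal RT law.
#' @param error_rate probability of a false-hit (wrong side) choice.
#' @param movement_time_mean_ms,movement_time_sd_ms movement-time law (normal,
#'   truncated at 50 ms).
#' @param iti_ms inter-trial interval inserted between trials.
#' @param seed master seed for the session.
#' @return object of class `task_config`.
#' @export
task_config <- function(n_trials = 186L,
                        foreperiod_range_ms = c(400, 800),
                        cue_duration_ms = 100,
                        catch_fraction = 0.167,
                        catch_hold_ms = 1000,
                        response_window_ms = 2100,
                        rt_mean_ms = c(V = 386.3, A = 394.9, AV = 322.4),
                        rt_sd_ms = c(V = 98.7, A = 101.6, AV = 86.5),
                        rt_shift_ms = 100,
                        error_rate = 0.15,
                        movement_time_mean_ms = 350,
                        movement_time_sd_ms = 80,
                        iti_ms = 2000,
                        seed = 1L) {
  cfg <- list(
    n_trials = as.integer(n_trials),
    foreperiod_range_ms = foreperiod_range_ms,
    cue_duration_ms = cue_duration_ms,
    catch_fraction = catch_fraction,
    catch_hold_ms = catch_hold_ms,
    response_window_ms = response_window_ms,
    rt_mean_ms = rt_mean_ms,
    rt_sd_ms = rt_sd_ms,
    rt_shift_ms = rt_shift_ms,
    error_rate = error_rate,
    movement_time_mean_ms = movement_time_mean_ms,
    movement_time_sd_ms = movement_time_sd_ms,
    iti_ms = iti_ms,
    seed = as.integer(seed)
  )
  validate_task_config(cfg)
  structure(cfg, class = "task_config")
}

validate_task_config <- function(cfg) {
  stopifnot(
    cfg$n_trials >= 0,
    cfg$catch_fraction >= 0, cfg$catch_fraction <= 1,
    length(cfg$foreperiod_range_ms) == 2L,
    cfg$foreperiod_range_ms[1] < cfg$foreperiod_range_ms[2],
    cfg$cue_duration_ms > 0, cfg$response_window_ms > 0,
    cfg$error_rate >= 0, cfg$error_rate <= 1
  )
  mods <- c("V", "A", "AV")
  if (!setequal(names(cfg$rt_mean_ms), mods) || !setequal(names(cfg$rt_sd_ms), mods)) {
    stop("rt_mean_ms and rt_sd_ms must be named over exactly {V, A, AV}")
  }
  if (!all(is.finite(cfg$rt_mean_ms)) || !all(is.finite(cfg$rt_sd_ms))) {
    stop("non-finite RT parameters in task_config")
  }
  if (any(cfg$rt_mean_ms <= cfg$rt_shift_ms)) {
    stop("rt_mean_ms must exceed rt_shift_ms for the shifted log-normal law")
  }
  invisible(cfg)
}

#' Draw reaction times from the generator's shifted log-normal law
#'
#' The RT model of the synthetic task: `shift + LogNormal(mu, sigma)` with
#' `mu`, `sigma` solved so the draw has the requested mean and SD. This is the
#' same sampler [generate_behavior()] uses, exposed so session-level RT
#' simulations (e.g. ANOVA calibration experiments) can draw RTs directly.
#'
#' @param n number of draws.
#' @param mean_ms,sd_ms target mean and SD of the RT in ms.
#' @param shift_ms lower shift of the law (default 100 ms).
#' @return numeric vector of RTs (ms), all `> shift_ms`.
#' @export
sample_rt <- function(n, mean_ms, sd_ms, shift_ms = 100) {
  stopifnot(is.finite(mean_ms), is.finite(sd_ms), mean_ms > shift_ms, sd_ms > 0)
  m <- mean_ms - shift_ms
  s2 <- log(1 + (sd_ms / m)^2)
  mu <- log(m) - s2 / 2
  shift_ms + stats::rlnorm(n, meanlog = mu, sdlog = sqrt(s2))
}

#' Generate the behavioral trial table of a synthetic session
#'
#' Draws catch flags (Bernoulli at `catch_fraction`), equiprobable modalities
#' and balanced sides for non-catch trials, uniform foreperiods, shifted
#' log-normal RTs per modality, and false-hit errors at `error_rate`. Error
#' trials receive `choice_side` opposite to `stimulus_side`. After an error,
#' the next scheduled non-catch trial repeats the same stimulus and is flagged
#' `is_correction_trial` (catch draws are never displaced, so the catch
#' fraction stays Bernoulli). Catch trials have no cue and a fixed hold.
#' All event times are in ms on a single session clock.
#'
#' @param config a [task_config()].
#' @return `data.frame` of class `trial_table`, one row per trial, with columns
#'   `trial_id, session_id, stimulus_side, modality, poke_in_ms, cue_on_ms,
#'   withdrawal_ms, choice_side, correct, rt_ms, movement_time_ms,
#'   is_correction_trial, injection_condition`.
#' @export
generate_behavior <- function(config) {
  validate_task_config(config)
  n <- config$n_trials
  empty <- data.frame(
    trial_id = integer(0), session_id = character(0),
    stimulus_side = character(0), modality = character(0),
    poke_in_ms = numeric(0), cue_on_ms = numeric(0), withdrawal_ms = numeric(0),
    choice_side = character(0), correct = logical(0), rt_ms = numeric(0),
    movement_time_ms = numeric(0), is_correction_trial = logical(0),
    injection_condition = character(0), stringsAsFactors = FALSE
  )
  if (n == 0L) return(structure(empty, class = c("trial_table", "data.frame")))

  local_seed(derive_seed(config$seed, "behavior"), {
    is_catch <- stats::runif(n) < config$catch_fraction
    modality <- ifelse(is_catch, "catch",
                       sample(c("V", "A", "AV"), n, replace = TRUE))
    side <- ifelse(is_catch, "none", sample(c("left", "right"), n, replace = TRUE))
    foreperiod <- stats::runif(n, config$foreperiod_range_ms[1],
                               config$foreperiod_range_ms[2])
    is_error <- !is_catch & stats::runif(n) < config$error_rate

    # correction procedure: the next scheduled non-catch trial after an error
    # repeats the erroneous trial's stimulus
    is_corr <- logical(n)
    if (n >= 2L) {
      pending <- NA_integer_
      for (i in seq_len(n)) {
        if (!is.na(pending) && !is_catch[i]) {
          modality[i] <- modality[pending]
          side[i] <- side[pending]
          is_corr[i] <- TRUE
          pending <- NA_integer_
        }
        if (!is_catch[i] && is_error[i]) pending <- i
      }
    }

    rt <- rep(NA_real_, n)
    for (m in c("V", "A", "AV")) {
      idx <- which(modality == m)
      if (length(idx)) {
        rt[idx] <- sample_rt(length(idx), config$rt_mean_ms[[m]],
                             config$rt_sd_ms[[m]], config$rt_shift_ms)
      }
    }
    mt <- pmax(50, stats::rnorm(n, config$movement_time_mean_ms,
                                config$movement_time_sd_ms))
    mt[is_catch] <- NA_real_

    choice <- ifelse(is_catch, "none",
                     ifelse(is_error, ifelse(side == "left", "right", "left"), side))

    # session clock: trials laid out sequentially with a fixed ITI
    hold <- ifelse(is_catch, config$catch_hold_ms, foreperiod + rt)
    trial_len <- hold + ifelse(is_catch, 0, mt) + config$iti_ms
    poke_in <- cumsum(c(0, trial_len[-n]))
    cue_on <- ifelse(is_catch, NA_real_, poke_in + foreperiod)
    withdrawal <- ifelse(is_catch, poke_in + config$catch_hold_ms, cue_on + rt)

    out <- data.frame(
      trial_id = seq_len(n), session_id = "synthetic",
      stimulus_side = side, modality = modality,
      poke_in_ms = poke_in, cue_on_ms = cue_on, withdrawal_ms = withdrawal,
      choice_side = choice, correct = ifelse(is_catch, TRUE, !is_error),
      rt_ms = rt, movement_time_ms = mt, is_correction_trial = is_corr,
      injection_condition = "none", stringsAsFactors = FALSE
    )
    structure(out, class = c("trial_table", "data.frame"))
  })
}
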