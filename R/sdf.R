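#' Trial-filtering rules feeding all downstream statistics
#'
#' * `neural`: correct, non-catch trials with RT >= 150 ms (short-RT trials
#'   are excluded so sensory-evoked activity does not bleed into the
#'   premovement epoch), correction repeats excluded by default.
#' * `behavior`: correct, non-catch trials.
#' * `error_analysis`: false-hit errors only (wrong-side pokes); callers must
#'   check the `sufficient` attribute (>= 4 such trials required).
#'
#' The operation is idempotent: filtering a filtered table is a no-op.
#'
#' @param trials a `trial_table`.
#' @param purpose one of `"neural"`, `"behavior"`, `"error_analysis"`.
#' @param min_rt_ms neural RT floor (default 150 ms).
#' @param include_corrections keep correction repeats in the neural set.
#' @param min_error_trials error-analysis sufficiency threshold.
#' @return filtered `trial_table`; for `error_analysis` with attribute
#'   `sufficient`.
#' @export
filter_trials <- function(trials,
                          purpose = c("neural", "behavior", "error_analysis"),
                          min_rt_ms = 150,
                          include_corrections = FALSE,
                          min_error_trials = 4L) {
  purpose <- match.arg(purpose)
  noncatch <- trials$modality != "catch"
  out <- switch(purpose,
    neural = {
      keep <- noncatch & trials$correct &
        !is.na(trials$rt_ms) & trials$rt_ms >= min_rt_ms
      if (!include_corrections) keep <- keep & !trials$is_correction_trial
      trials[keep, , drop = FALSE]
    },
    behavior = trials[noncatch & trials$correct, , drop = FALSE],
    error_analysis = {
      keep <- noncatch & !trials$correct & trials$choice_side != "none"
      trials[keep, , drop = FALSE]
    }
  )
  if (purpose == "error_analysis") {
    attr(out, "sufficient") <- nrow(out) >= min_error_trials
  }
  out
}

#' Alignment specification for event-aligned analyses
#'
#' @param align_event `"cue_on"` or `"withdrawal"`.
#' @param window_ms numeric length-2 `(pre, post)` relative to the event.
#' @param kernel_sigma_ms Gaussian kernel SD (15 ms default; 4 ms is used for
#'   sensory-response analyses).
#' @param grid_step_ms time-grid step.
#' @return object of class `alignment_spec`.
#' @export
alignment_spec <- function(align_event = c("withdrawal", "cue_on"),
                           window_ms = c(-400, 200),
                           kernel_sigma_ms = 15,
                           grid_step_ms = 1) {
  align_event <- match.arg(align_event)
  stopifnot(window_ms[1] < window_ms[2], kernel_sigma_ms > 0, grid_step_ms > 0)
  structure(list(align_event = align_event, window_ms = window_ms,
                 kernel_sigma_ms = kernel_sigma_ms,
                 grid_step_ms = grid_step_ms),
            class = "alignment_spec")
}

anchor_times <- function(trials, align_event) {
  switch(align_event,
         cue_on = trials$cue_on_ms,
         withdrawal = trials$withdrawal_ms,
         stop("unknown alignment event: ", align_event))
}

# Gaussian kernel truncated at ±4 sigma, pedestal-subtracted so it reaches 0
# continuously at the cutoff, and renormalized to unit area per ms (rates are
# scaled to sp/s by the caller). The continuous taper keeps trapezoid
# integration of the gridded SDF accurate to ~1e-7 per spike.
gauss_kernel <- function(u, sigma) {
  ped <- stats::dnorm(4)
  z <- sigma * (2 * (stats::pnorm(4) - 0.5) - 8 * ped)
  ifelse(abs(u) <= 4 * sigma,
         (stats::dnorm(u / sigma) - ped) / z, 0)
}

#' Compute event-aligned spike density functions
#'
#' Per trial, spikes within the window padded by 4 kernel SDs are convolved
#' with a unit-area Gaussian kernel (truncated at ±4 SD and renormalized) and
#' evaluated on a uniform grid. Rates are in sp/s.
#'
#' @param spikes a `unit_spikes` object.
#' @param trials a `trial_table` with resolved anchor events.
#' @param spec an [alignment_spec()].
#' @return object of class `sdf_matrix`: `list(unit_id, trial_ids, time,
#'   rate)` with `rate` a trials x time matrix.
#' @export
compute_sdf <- function(spikes, trials, spec = alignment_spec()) {
  anchors <- anchor_times(trials, spec$align_event)
  grid <- seq(spec$window_ms[1], spec$window_ms[2], by = spec$grid_step_ms)
  pad <- 4 * spec$kernel_sigma_ms
  rate <- matrix(0, nrow = nrow(trials), ncol = length(grid))
  for (i in seq_len(nrow(trials))) {
    if (is.na(anchors[i])) next
    rel <- spikes$spike_times_ms - anchors[i]
    rel <- rel[rel >= spec$window_ms[1] - pad & rel < spec$window_ms[2] + pad]
    if (!length(rel)) next
    rate[i, ] <- 1000 * colSums(gauss_kernel(outer(rel, grid, function(s, t) t - s),
                                             spec$kernel_sigma_ms))
  }
  structure(list(unit_id = spikes$unit_id, trial_ids = trials$trial_id,
                 time = grid, rate = rate, spec = spec),
            class = "sdf_matrix")
}

#' Integrate SDF rows over the window (trapezoid rule)
#'
#' For spikes at least 4 kernel SDs inside the window the integral of a row
#' recovers the spike count (kernel normalization).
#'
#' @param sdf an `sdf_matrix`.
#' @return numeric vector, one integral (in spikes) per trial.
#' @export
sdf_integral <- function(sdf) {
  dt <- diff(sdf$time)
  apply(sdf$rate, 1, function(r) {
    sum((r[-length(r)] + r[-1]) / 2 * dt) / 1000
  })
}

#' Mean firing rate in an event-anchored epoch
#'
#' Counts spikes in the half-open interval `[anchor + interval[1],
#' anchor + interval[2])` per trial and divides by the epoch duration.
#' The three standard epochs are: baseline `[-100, 0)` before cue onset,
#' evoked `[0, 100)` after cue onset, premovement `[-100, 0)` before
#' withdrawal.
#'
#' @param spikes a `unit_spikes` object.
#' @param trials a `trial_table`.
#' @param anchor `"cue_on"` or `"withdrawal"`.
#' @param interval_ms numeric length-2 epoch bounds relative to the anchor.
#' @return numeric vector of per-trial rates (sp/s); `NA` where the anchor is
#'   missing.
#' @export
epoch_rate <- function(spikes, trials,
                       anchor = c("withdrawal", "cue_on"),
                       interval_ms = c(-100, 0)) {
  anchor <- match.arg(anchor)
  stopifnot(interval_ms[1] < interval_ms[2])
  anchors <- anchor_times(trials, anchor)
  len_s <- (interval_ms[2] - interval_ms[1]) / 1000
  vapply(anchors, function(a) {
    if (is.na(a)) return(NA_real_)
    count_in(spikes$spike_times_ms, a + interval_ms[1], a + interval_ms[2]) / len_s
  }, numeric(1))
}

#' Standard epoch definitions
#'
#' @return data.frame with `name`, `anchor`, `lo`, `hi` (ms) for the
#'   baseline, evoked and premovement epochs.
#' @export
epoch_definitions <- function() {
  data.frame(
    name = c("baseline", "evoked", "premovement"),
    anchor = c("cue_on", "cue_on", "withdrawal"),
    lo = c(-100, 0, -100), hi = c(0, 100, 0),
    stringsAsFactors = FALSE
  )
}

#' Split trials at the median RT and average SDFs per half
#'
#' Ties at the median go to the fast half (deterministic rule).
#'
#' @param sdf an `sdf_matrix`.
#' @param trials the `trial_table` the SDF was computed from (same order).
#' @return list with `fast` and `slow` mean-SDF vectors, the `time` grid and
#'   the trial indices of each half.
#' @export
median_split_sdf <- function(sdf, trials) {
  stopifnot(nrow(trials) == nrow(sdf$rate))
  if (nrow(trials) < 2L) stop("median split needs at least 2 trials")
  med <- stats::median(trials$rt_ms)
  fast <- which(trials$rt_ms <= med)
  slow <- which(trials$rt_ms > med)
  list(
    fast = colMeans(sdf$rate[fast, , drop = FALSE]),
    slow = colMeans(sdf$rate[slow, , drop = FALSE]),
    time = sdf$time, fast_idx = fast, slow_idx = slow
  )
}
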