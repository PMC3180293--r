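#' Spike detection configuration
#'
#' Defaults follow the recording front-end: 0.8--5 kHz band-pass, RMS power in
#' a 0.2-ms sliding window at 25 kHz, detection at mean power + 5 SD, 32-sample
#' waveforms.
#'
#' @param bandpass_hz numeric length-2 band edges.
#' @param power_window_ms RMS window width.
#' @param threshold_k SD multiplier of the power threshold.
#' @param waveform_samples extracted waveform length.
#' @param trough_sample alignment sample of the trough within the waveform.
#' @param fs_hz sampling rate.
#' @param filter_order Butterworth order (applied forward and backward, so the
#'   effective attenuation is doubled).
#' @return object of class `detection_config`.
#' @export
detection_config <- function(bandpass_hz = c(800, 5000),
                             power_window_ms = 0.2,
                             threshold_k = 5,
                             waveform_samples = 32L,
                             trough_sample = 10L,
                             fs_hz = 25000,
                             filter_order = 3L) {
  stopifnot(length(bandpass_hz) == 2L, bandpass_hz[1] < bandpass_hz[2],
            power_window_ms > 0, waveform_samples > 0,
            trough_sample >= 1, trough_sample <= waveform_samples)
  if (bandpass_hz[2] >= fs_hz / 2) {
    stop("upper band edge must be below the Nyquist frequency fs_hz/2")
  }
  structure(list(bandpass_hz = bandpass_hz, power_window_ms = power_window_ms,
                 threshold_k = threshold_k,
                 waveform_samples = as.integer(waveform_samples),
                 trough_sample = as.integer(trough_sample),
                 fs_hz = fs_hz, filter_order = as.integer(filter_order)),
            class = "detection_config")
}

#' Zero-phase band-pass filter of a wideband trace
#'
#' Butterworth band-pass (order `config$filter_order`) applied with
#' [signal::filtfilt()], so the output is zero-phase and the same length as
#' the input. Operates row-wise on multichannel matrices.
#'
#' @param trace numeric vector or channels-x-samples matrix.
#' @param config a [detection_config()].
#' @return filtered trace, same shape.
#' @export
bandpass <- function(trace, config = detection_config()) {
  bf <- signal::butter(config$filter_order,
                       config$bandpass_hz / (config$fs_hz / 2), type = "pass")
  apply_rows <- function(x) as.numeric(signal::filtfilt(bf, x))
  if (is.matrix(trace)) {
    t(apply(trace, 1, apply_rows))
  } else {
    apply_rows(trace)
  }
}

# sliding RMS power, centered window of `win` samples (same length as input)
sliding_rms <- function(x, win) {
  n <- length(x)
  if (n < win) stop("trace shorter than the RMS window")
  cs <- cumsum(c(0, x^2))
  half_lo <- floor((win - 1) / 2)
  half_hi <- win - 1 - half_lo
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}

#' Detect spike events from a filtered trace by sliding-window RMS power
#'
#' The RMS power of each channel is computed in a 0.2-ms sliding window; the
#' per-channel threshold is the mean power plus `threshold_k` times the SD of
#' the power over time. Samples where any channel's power exceeds its
#' threshold are merged into events when closer than one waveform span, and
#' each event is aligned to the voltage trough (most negative sample across
#' channels within the event span).
#'
#' @param filtered numeric vector or channels-x-samples matrix (already
#'   band-passed).
#' @param config a [detection_config()].
#' @return integer vector of trough-aligned event sample indices (1-based).
#' @export
detect_spikes <- function(filtered, config = detection_config()) {
  if (!is.matrix(filtered)) filtered <- matrix(filtered, nrow = 1)
  win <- max(1L, round(config$power_window_ms * config$fs_hz / 1000))
  n <- ncol(filtered)
  above <- rep(FALSE, n)
  for (ch in seq_len(nrow(filtered))) {
    p <- sliding_rms(filtered[ch, ], win)
    thr <- mean(p) + config$threshold_k * stats::sd(p)
    above <- above | (p > thr)
  }
  idx <- which(above)
  if (!length(idx)) return(integer(0))

  span <- config$waveform_samples
  gap_starts <- c(TRUE, diff(idx) > span)
  event_id <- cumsum(gap_starts)
  vapply(split(idx, event_id), function(samples) {
    lo <- max(1L, min(samples) - span %/% 2)
    hi <- min(n, max(samples) + span %/% 2)
    seg <- filtered[, lo:hi, drop = FALSE]
    trough_col <- which.min(apply(seg, 2, min))
    as.integer(lo + trough_col - 1L)
  }, integer(1), USE.NAMES = FALSE)
}

#' Extract fixed-length waveforms around detected events
#'
#' Each event contributes `waveform_samples` samples per channel, aligned so
#' the event index falls on `trough_sample`. Events too close to the trace
#' edges are dropped; the drop count is attached as attribute `n_dropped`.
#'
#' @param trace numeric vector or channels-x-samples matrix.
#' @param events integer event sample indices.
#' @param config a [detection_config()].
#' @return numeric array `n_events x waveform_samples x n_channels` with
#'   attribute `n_dropped`.
#' @export
extract_waveforms <- function(trace, events, config = detection_config()) {
  if (!is.matrix(trace)) trace <- matrix(trace, nrow = 1)
  n <- ncol(trace)
  pre <- config$trough_sample - 1L
  post <- config$waveform_samples - config$trough_sample
  ok <- events - pre >= 1L & events + post <= n
  kept <- events[ok]
  out <- array(NA_real_,
               dim = c(length(kept), config$waveform_samples, nrow(trace)))
  for (e in seq_along(kept)) {
    span <- (kept[e] - pre):(kept[e] + post)
    out[e, , ] <- t(trace[, span, drop = FALSE])
  }
  attr(out, "n_dropped") <- sum(!ok)
  attr(out, "events") <- kept
  out
}

#' Fraction of inter-spike intervals violating the refractory period
#'
#' @param spike_times_ms sorted spike times (ms).
#' @param refractory_ms refractory period (default 1.5 ms; the published
#'   criterion states the <1% rule but not the period).
#' @return proportion of the `n - 1` intervals shorter than `refractory_ms`.
#' @export
refractory_violation_fraction <- function(spike_times_ms, refractory_ms = 1.5) {
  n <- length(spike_times_ms)
  if (n < 2L) {
    warning("fewer than 2 spikes; returning 0")
    return(0)
  }
  if (is.unsorted(spike_times_ms)) stop("spike times must be sorted")
  mean(diff(spike_times_ms) < refractory_ms)
}

#' Isolation distance of a spike cluster
#'
#' Squared Mahalanobis distances of all non-cluster spikes to the cluster
#' center, using the cluster's own covariance; the statistic is the distance
#' of the `n_c`-th closest non-cluster spike, where `n_c` is the cluster size.
#' When fewer than `n_c` non-cluster spikes exist the maximum distance is
#' returned with attribute `capped = TRUE`.
#'
#' @param cluster_features numeric matrix, cluster spikes x features.
#' @param other_features numeric matrix, non-cluster spikes x features.
#' @return nonnegative scalar (squared Mahalanobis distance).
#' @export
isolation_distance <- function(cluster_features, other_features) {
  cluster_features <- as.matrix(cluster_features)
  other_features <- as.matrix(other_features)
  n_c <- nrow(cluster_features)
  d <- ncol(cluster_features)
  if (n_c < d + 1L) stop("cluster must have at least dim + 1 spikes")
  if (!nrow(other_features)) stop("non-cluster set is empty")
  S <- stats::cov(cluster_features)
  if (rcond_sym(S) < 1e-12) {
    stop("singular cluster covariance; reduce or decorrelate the feature set")
  }
  md <- stats::mahalanobis(other_features, colMeans(cluster_features), S)
  if (nrow(other_features) < n_c) {
    return(structure(max(md), capped = TRUE))
  }
  sort(md)[n_c]
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' Waveform feature set for cluster quality metrics
#'
#' Per channel: energy, peak, valley, and the first two principal components
#' of the waveform set (PCs computed on the set under analysis).
#'
#' @param waveforms array `n_events x n_samples x n_channels` from
#'   [extract_waveforms()].
#' @return numeric matrix, events x (5 per channel) features.
#' @export
waveform_features <- function(waveforms) {
  stopifnot(length(dim(waveforms)) == 3L)
  n_ch <- dim(waveforms)[3]
  feats <- lapply(seq_len(n_ch), function(ch) {
    w <- waveforms[, , ch, drop = TRUE]
    if (is.null(dim(w))) w <- matrix(w, nrow = 1)
    pcs <- stats::prcomp(w, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
    cbind(energy = rowSums(w^2),
          peak = apply(w, 1, max),
          valley = apply(w, 1, min),
          pc1 = pcs[, 1], pc2 = pcs[, 2])
  })
  do.call(cbind, feats)
}

#' Single-unit acceptance rule
#'
#' A cluster counts as a well-isolated single unit iff its refractory
#' violation fraction is below 1% and its isolation distance exceeds 20.
#'
#' @param violation_fraction from [refractory_violation_fraction()].
#' @param iso_distance from [isolation_distance()].
#' @return logical flag.
#' @export
accept_unit <- function(violation_fraction, iso_distance) {
  violation_fraction < 0.01 && iso_distance > 20
}
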