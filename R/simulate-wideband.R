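#' Canonical 32-sample extracellular spike template
#'
#' Biphasic waveform (sharp negative trough followed by a slower positive
#' rebound) with its trough at sample 10, unit trough amplitude. Scaled by
#' callers to the desired peak amplitude in microvolts.
#'
#' @param n_samples template length (default 32).
#' @param trough_sample index of the trough (default 10).
#' @return numeric vector of length `n_samples` with `min == -1`.
#' @export
spike_template <- function(n_samples = 32L, trough_sample = 10L) {
  i <- seq_len(n_samples) - trough_sample
  w <- -exp(-(i / 2.2)^2) + 0.45 * exp(-((i - 6) / 5)^2)
  w / abs(min(w))
}

#' Synthesize a tetrode wideband voltage trace from ground-truth spike trains
#'
#' Gaussian noise plus the spike template added at each ground-truth spike
#' time; the template is replicated on the four tetrode channels with
#' per-channel amplitude scaling. Spikes at identical times superpose
#' (amplitudes sum). Times are rounded to the nearest sample.
#'
#' @param spikes list of `unit_spikes` (or a single one).
#' @param duration_ms trace duration; spike times beyond it are dropped.
#' @param template waveform added per spike (trough-normalized to -1).
#' @param amplitude_uv trough amplitude per unit, recycled over units.
#' @param channel_gains per-channel scaling (length = channel count).
#' @param noise_sd_uv Gaussian noise SD in microvolts.
#' @param fs_hz sampling rate (default 25 kHz).
#' @param seed seed for the noise stream.
#' @return list of class `wideband_trace`: `trace` (channels x samples
#'   matrix, microvolts), `fs_hz`, `spike_index` (ground-truth trough sample
#'   per spike, ascending), `spike_unit` (unit id per spike).
#' @export
synthesize_wideband <- function(spikes, duration_ms,
                                template = spike_template(),
                                amplitude_uv = 100,
                                channel_gains = c(1, 0.8, 0.6, 0.4),
                                noise_sd_uv = 10,
                                fs_hz = 25000,
                                seed = 1L) {
  if (inherits(spikes, "unit_spikes")) spikes <- list(spikes)
  stopifnot(length(template) == 32L, noise_sd_uv >= 0, fs_hz > 0)
  n_samp <- ceiling(duration_ms * fs_hz / 1000)
  n_ch <- length(channel_gains)
  amplitude_uv <- rep_len(amplitude_uv, length(spikes))
  trough <- 10L

  trace <- if (noise_sd_uv > 0) {
    local_seed(seed, matrix(stats::rnorm(n_ch * n_samp, sd = noise_sd_uv),
                            nrow = n_ch))
  } else {
    matrix(0, nrow = n_ch, ncol = n_samp)
  }

  idx_all <- integer(0)
  unit_all <- integer(0)
  for (u in seq_along(spikes)) {
    st <- spikes[[u]]$spike_times_ms
    centers <- round(st * fs_hz / 1000) + 1L
    keep <- centers - (trough - 1L) >= 1L & centers + (32L - trough) <= n_samp
    centers <- centers[keep]
    for (cc in centers) {
      span <- (cc - trough + 1L):(cc + 32L - trough)
      for (ch in seq_len(n_ch)) {
        trace[ch, span] <- trace[ch, span] +
          amplitude_uv[u] * channel_gains[ch] * template
      }
    }
    idx_all <- c(idx_all, centers)
    unit_all <- c(unit_all, rep(spikes[[u]]$unit_id, length(centers)))
  }
  ord <- order(idx_all)
  structure(list(trace = trace, fs_hz = fs_hz,
                 spike_index = idx_all[ord], spike_unit = unit_all[ord]),
            class = "wideband_trace")
}
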