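#' Area under the ROC curve between two rate samples
#'
#' Rank-based (Mann--Whitney) computation: the probability that a random draw
#' from `values_a` exceeds one from `values_b`, with ties counted one half.
#' Equals the brute-force fraction of winning pairs.
#'
#' @param values_a,values_b nonempty numeric samples.
#' @return area in `[0, 1]`; 0.5 means indistinguishable distributions.
#' @export
roc_area <- function(values_a, values_b) {
  n_a <- length(values_a)
  n_b <- length(values_b)
  if (!n_a || !n_b) stop("both samples must be nonempty")
  r <- rank(c(values_a, values_b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u / (n_a * n_b)
}

#' Scaled ROC discrimination index
#'
#' `2 * roc_area - 1`, scaling the area to `[-1, 1]` where 0 reflects no
#' difference and the sign denotes which condition carries the higher rates
#' (positive = `values_a`). Antisymmetric under swapping the samples.
#'
#' @inheritParams roc_area
#' @return index in `[-1, 1]`.
#' @export
roc_index <- function(values_a, values_b) {
  n_a <- length(values_a)
  n_b <- length(values_b)
  if (!n_a || !n_b) stop("both samples must be nonempty")
  r <- rank(c(values_a, values_b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  # single division of the exactly-representable numerator, so swapping the
  # samples negates the numerator and flips the sign bit-exactly
  (2 * u - n_a * n_b) / (n_a * n_b)
}

#' Permutation test of a scaled ROC index
#'
#' Group labels are shuffled `n_perm` times preserving group sizes; the
#' two-sided p-value is `(1 + #{|index_perm| >= |index_obs|}) / (n_perm + 1)`
#' (add-one correction, so p is never 0 and the minimum attainable p at the
#' default 500 repetitions is 1/501).
#'
#' @inheritParams roc_area
#' @param n_perm number of permutations (default 500).
#' @param seed optional seed for the shuffle stream.
#' @return list of class `roc_result`: `index`, `p_value`, `n_a`, `n_b`,
#'   `n_perm`.
#' @export
roc_permutation_test <- function(values_a, values_b, n_perm = 500, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  n_a <- length(values_a)
  n_b <- length(values_b)
  obs <- roc_index(values_a, values_b)
  pooled_ranks <- rank(c(values_a, values_b))
  n <- n_a + n_b
  # index from the ranks of the A-group positions; shuffling labels is
  # equivalent to sampling which positions belong to A
  idx_from_ranks <- function(pos) {
    u <- sum(pooled_ranks[pos]) - n_a * (n_a + 1) / 2
    (2 * u - n_a * n_b) / (n_a * n_b)
  }
  perm <- local_seed(seed, {
    vapply(seq_len(n_perm),
           function(k) idx_from_ranks(sample.int(n, n_a)),
           numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  structure(list(index = obs, p_value = p, n_a = n_a, n_b = n_b,
                 n_perm = n_perm),
            class = "roc_result")
}

#' Sliding-window time course of the scaled ROC index
#'
#' Windows of `width_ms` stepped by `step_ms` are placed fully inside the
#' shared time grid (centers at grid start + width/2 + k*step). Per window,
#' each trial contributes its mean SDF rate over the half-open window, and
#' the two trial sets feed [roc_permutation_test()].
#'
#' @param sdf_a,sdf_b `sdf_matrix` objects on the same time grid (condition A
#'   and B trial sets).
#' @param width_ms,step_ms window geometry (defaults 100 / 20 ms).
#' @param n_perm permutations per window.
#' @param seed seed; per-window streams are derived from it.
#' @return list of class `roc_timecourse`: `window_centers_ms`, `index`,
#'   `p_value`, `significant` (p < alpha), `alpha`, `width_ms`, `step_ms`.
#' @export
roc_timecourse <- function(sdf_a, sdf_b, width_ms = 100, step_ms = 20,
                           n_perm = 500, seed = NULL, alpha = 0.05) {
  if (!isTRUE(all.equal(sdf_a$time, sdf_b$time))) {
    stop("the two SDF matrices must share one time grid")
  }
  grid <- sdf_a$time
  span <- grid[length(grid)] - grid[1]
  if (span < width_ms) stop("time grid shorter than one window")
  centers <- seq(grid[1] + width_ms / 2, grid[length(grid)] - width_ms / 2,
                 by = step_ms)
  idx <- numeric(length(centers))
  pval <- numeric(length(centers))
  for (k in seq_along(centers)) {
    lo <- centers[k] - width_ms / 2
    hi <- centers[k] + width_ms / 2
    cols <- grid >= lo & grid < hi
    a <- rowMeans(sdf_a$rate[, cols, drop = FALSE])
    b <- rowMeans(sdf_b$rate[, cols, drop = FALSE])
    res <- roc_permutation_test(a, b, n_perm = n_perm,
                                seed = if (is.null(seed)) NULL
                                       else derive_seed(seed, paste0("win_", k)))
    idx[k] <- res$index
    pval[k] <- res$p_value
  }
  structure(list(window_centers_ms = centers, index = idx, p_value = pval,
                 significant = pval < alpha, alpha = alpha,
                 width_ms = width_ms, step_ms = step_ms),
            class = "roc_timecourse")
}

#' Center of mass of significant positive preference windows
#'
#' `sum(t_i * index_i) / sum(index_i)` over windows with a significant
#' positive index; `NA` (undefined) when no such window exists.
#'
#' @param tc a `roc_timecourse`.
#' @return time in ms, or `NA_real_` with attribute `defined = FALSE`.
#' @export
center_of_mass <- function(tc) {
  sel <- tc$significant & tc$index > 0
  if (!any(sel)) {
    return(structure(NA_real_, defined = FALSE))
  }
  structure(sum(tc$window_centers_ms[sel] * tc$index[sel]) / sum(tc$index[sel]),
            defined = TRUE)
}

#' Premovement activity index of one unit
#'
#' Scaled ROC index contrasting the premovement epoch (100 ms before
#' withdrawal) against the prestimulation baseline epoch (100 ms before cue
#' onset) over neural-filtered trials, with permutation significance.
#' Positive = premovement rates exceed baseline.
#'
#' @param spikes a `unit_spikes` object.
#' @param trials neural-filtered `trial_table`.
#' @param n_perm,seed forwarded to [roc_permutation_test()].
#' @return a `roc_result`.
#' @export
premovement_index <- function(spikes, trials, n_perm = 500, seed = NULL) {
  pre <- epoch_rate(spikes, trials, "withdrawal", c(-100, 0))
  base <- epoch_rate(spikes, trials, "cue_on", c(-100, 0))
  ok <- !is.na(pre) & !is.na(base)
  roc_permutation_test(pre[ok], base[ok], n_perm = n_perm, seed = seed)
}

#' Direction preference index of one unit
#'
#' Scaled ROC index contrasting premovement-epoch rates on contraversive
#' versus ipsiversive movement trials (movement coded by `choice_side`
#' relative to the recorded hemisphere). Positive = contralateral preference.
#'
#' @param spikes a `unit_spikes` object.
#' @param trials `trial_table` (typically neural-filtered).
#' @param hemisphere recorded hemisphere.
#' @param epoch_anchor,epoch_ms epoch (defaults: premovement).
#' @param n_perm,seed forwarded to [roc_permutation_test()].
#' @return a `roc_result`, or `NULL` when either direction has no trials.
#' @export
direction_preference <- function(spikes, trials, hemisphere = "left",
                                 epoch_anchor = "withdrawal",
                                 epoch_ms = c(-100, 0),
                                 n_perm = 500, seed = NULL) {
  dir <- movement_direction(trials$choice_side, hemisphere)
  rates <- epoch_rate(spikes, trials, epoch_anchor, epoch_ms)
  a <- rates[dir == "contra" & !is.na(rates)]
  b <- rates[dir == "ipsi" & !is.na(rates)]
  if (!length(a) || !length(b)) return(NULL)
  roc_permutation_test(a, b, n_perm = n_perm, seed = seed)
}

#' Direction preference on correct versus false-hit error trials
#'
#' Premovement-epoch direction preference computed separately on the
#' neural-filtered correct set and on the false-hit error set (grouping by
#' movement direction in both). Requires at least `min_error_trials` errors,
#' otherwise an `insufficient` flag is returned.
#'
#' @param spikes a `unit_spikes` object.
#' @param trials full session `trial_table`.
#' @param hemisphere recorded hemisphere.
#' @param min_error_trials minimum false-hit error count (default 4).
#' @param n_perm,seed forwarded to the underlying tests.
#' @return list with `sufficient`, and when sufficient `index_correct`,
#'   `index_error`, `n_error`.
#' @export
correct_vs_error_preference <- function(spikes, trials, hemisphere = "left",
                                        min_error_trials = 4L,
                                        n_perm = 500, seed = NULL) {
  errors <- filter_trials(trials, "error_analysis",
                          min_error_trials = min_error_trials)
  if (!isTRUE(attr(errors, "sufficient"))) {
    return(list(sufficient = FALSE, n_error = nrow(errors)))
  }
  correct <- filter_trials(trials, "neural")
  rc <- direction_preference(spikes, correct, hemisphere,
                             n_perm = n_perm,
                             seed = if (is.null(seed)) NULL else derive_seed(seed, "corr"))
  re <- direction_preference(spikes, errors, hemisphere,
                             n_perm = n_perm,
                             seed = if (is.null(seed)) NULL else derive_seed(seed, "err"))
  if (is.null(rc) || is.null(re)) return(list(sufficient = FALSE, n_error = nrow(errors)))
  list(sufficient = TRUE, index_correct = rc$index, index_error = re$index,
       n_error = nrow(errors))
}
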