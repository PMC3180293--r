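#' Trial-by-trial correlation between premovement rate and reaction time
#'
#' Pearson correlation with its two-sided significance. Zero variance in
#' either variable yields an undefined-correlation flag (such units are
#' excluded from population statistics).
#'
#' @param rates per-trial premovement rates (sp/s), neural-filtered trials of
#'   one movement direction.
#' @param rt_ms matching reaction times.
#' @return list of class `correlation_result`: `r`, `p_value`, `n_trials`,
#'   `defined`.
#' @export
rt_rate_correlation <- function(rates, rt_ms) {
  stopifnot(length(rates) == length(rt_ms))
  ok <- !is.na(rates) & !is.na(rt_ms)
  rates <- rates[ok]
  rt_ms <- rt_ms[ok]
  n <- length(rates)
  if (n < 3L || stats::sd(rates) == 0 || stats::sd(rt_ms) == 0) {
    return(structure(list(r = NA_real_, p_value = NA_real_, n_trials = n,
                          defined = FALSE), class = "correlation_result"))
  }
  ct <- stats::cor.test(rates, rt_ms, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n_trials = n,
                 defined = TRUE), class = "correlation_result")
}

#' Classify a unit's movement-related type from index and correlation signs
#'
#' Quadrant rule: type 1 = positive premovement index and positive RT--rate
#' correlation; type 2 = positive index, negative correlation; type 3 =
#' negative index, positive correlation; type 4 = negative index, negative
#' correlation. Units without significant premovement activity (permutation
#' p >= 0.05 against baseline) are unclassified, as are exact zeros of either
#' quantity. The `representative` flag additionally requires both magnitudes
#' to exceed `threshold` (default 0.1), removing data near the category
#' boundaries.
#'
#' @param premove_index scaled ROC premovement activity index.
#' @param premove_p its permutation p-value.
#' @param r Pearson RT--rate correlation (may be `NA` when undefined).
#' @param threshold representativeness threshold on both magnitudes.
#' @param alpha significance level of the premovement gate.
#' @return list of class `type_label`: `label` in
#'   `c("1","2","3","4","unclassified")` and `representative`.
#' @export
classify_neuron <- function(premove_index, premove_p, r,
                            threshold = 0.1, alpha = 0.05) {
  undefined <- is.na(r) || is.na(premove_index) || is.na(premove_p)
  if (undefined || premove_p >= alpha || premove_index == 0 || r == 0) {
    return(structure(list(label = "unclassified", representative = FALSE),
                     class = "type_label"))
  }
  label <- if (premove_index > 0 && r > 0) "1"
           else if (premove_index > 0 && r < 0) "2"
           else if (premove_index < 0 && r > 0) "3"
           else "4"
  rep_flag <- abs(premove_index) > threshold && abs(r) > threshold
  structure(list(label = label, representative = rep_flag),
            class = "type_label")
}

#' Multisensory modulation index (MSI)
#'
#' Bounded contrast between the audiovisual-condition mean rate and the
#' average of the unisensory mean rates:
#' `MSI = (AV - UNIave) / (AV + UNIave)` with `UNIave = (V + A) / 2`.
#' Positive values indicate multisensory enhancement, negative values
#' depression; the index is scale-invariant and lies in `(-1, 1)` for
#' positive rates. When both terms are zero the index is 0 and flagged
#' degenerate.
#'
#' @param av_rate,v_rate,a_rate mean firing rates (sp/s, >= 0) in the epoch
#'   under study (premovement by default; sensory windows for evoked-response
#'   comparisons).
#' @return list of class `msi_result`: `msi`, `av_rate`, `v_rate`, `a_rate`,
#'   `degenerate`.
#' @export
msi <- function(av_rate, v_rate, a_rate) {
  if (any(c(av_rate, v_rate, a_rate) < 0)) stop("rates must be nonnegative")
  uni <- (v_rate + a_rate) / 2
  degenerate <- (av_rate + uni) == 0
  value <- if (degenerate) 0 else (av_rate - uni) / (av_rate + uni)
  structure(list(msi = value, av_rate = av_rate, v_rate = v_rate,
                 a_rate = a_rate, degenerate = degenerate),
            class = "msi_result")
}

#' Full analysis profile of one unit
#'
#' Runs the premovement pipeline per movement direction: premovement activity
#' index with permutation significance, direction preference, RT--rate
#' correlation, type classification, and premovement MSI from the
#' per-modality mean rates. Returns a two-row data.frame (contra / ipsi).
#'
#' @param spikes a `unit_spikes` object.
#' @param trials full session `trial_table`.
#' @param hemisphere recorded hemisphere.
#' @param n_perm permutations for the index tests.
#' @param seed master seed for this unit's tests.
#' @param threshold classification threshold.
#' @return data.frame with one row per direction: `unit_id`, `direction`,
#'   `n_trials`, `premove_index`, `premove_p`, `r`, `r_p`, `type`,
#'   `representative`, `msi`, `av_rate`, `v_rate`, `a_rate`,
#'   `generated_type` (ground truth when available, else `NA`).
#' @export
unit_profile <- function(spikes, trials, hemisphere = "left",
                         n_perm = 500, seed = NULL, threshold = 0.1) {
  neural <- filter_trials(trials, "neural")
  dir_all <- movement_direction(neural$choice_side, hemisphere)
  rows <- lapply(c("contra", "ipsi"), function(d) {
    sel <- neural[dir_all == d, , drop = FALSE]
    base_row <- data.frame(
      unit_id = spikes$unit_id, direction = d, n_trials = nrow(sel),
      premove_index = NA_real_, premove_p = NA_real_,
      r = NA_real_, r_p = NA_real_,
      type = "unclassified", representative = FALSE,
      msi = NA_real_, av_rate = NA_real_, v_rate = NA_real_, a_rate = NA_real_,
      generated_type = if (!is.null(spikes$ground_truth))
        spikes$ground_truth$generated_type_label else NA_character_,
      stringsAsFactors = FALSE
    )
    if (nrow(sel) < 3L) return(base_row)
    pm <- premovement_index(spikes, sel, n_perm = n_perm,
                            seed = if (is.null(seed)) NULL
                                   else derive_seed(seed, paste0("pm_", d)))
    rates <- epoch_rate(spikes, sel, "withdrawal", c(-100, 0))
    corr <- rt_rate_correlation(rates, sel$rt_ms)
    cls <- classify_neuron(pm$index, pm$p_value, corr$r, threshold = threshold)
    mod_rate <- function(m) {
      v <- rates[sel$modality == m]
      if (length(v)) mean(v) else NA_real_
    }
    av <- mod_rate("AV"); v <- mod_rate("V"); a <- mod_rate("A")
    m <- if (!any(is.na(c(av, v, a)))) msi(av, v, a)$msi else NA_real_
    base_row$premove_index <- pm$index
    base_row$premove_p <- pm$p_value
    base_row$r <- corr$r
    base_row$r_p <- corr$p_value
    base_row$type <- cls$label
    base_row$representative <- cls$representative
    base_row$msi <- m
    base_row$av_rate <- av; base_row$v_rate <- v; base_row$a_rate <- a
    base_row
  })
  do.call(rbind, rows)
}

#' Population summary over unit profiles
#'
#' Per-direction type fractions among classified units, one-sample t-tests of
#' the correlation coefficients against zero, and mean MSI per type with
#' one-sample t-tests. Groups with fewer than 2 units are reported with the
#' test skipped (`NA` p, flagged).
#'
#' @param profiles data.frame rbind-ed from [unit_profile()] calls.
#' @return list with `type_fractions` (direction x type), `r_tests`
#'   (per-direction mean, SD, t, p), `msi_by_type` (per direction x type:
#'   mean MSI, n, p, `tested`).
#' @export
population_summary <- function(profiles) {
  stopifnot(nrow(profiles) >= 1L)
  dirs <- c("contra", "ipsi")
  types <- c("1", "2", "3", "4")

  type_fractions <- sapply(dirs, function(d) {
    sub <- profiles[profiles$direction == d, ]
    n <- nrow(sub)
    if (!n) return(stats::setNames(rep(NA_real_, length(types) + 1),
                                   c(types, "unclassified")))
    tab <- table(factor(sub$type, levels = c(types, "unclassified")))
    as.numeric(tab) / n
  })
  rownames(type_fractions) <- c(types, "unclassified")

  r_tests <- do.call(rbind, lapply(dirs, function(d) {
    rs <- profiles$r[profiles$direction == d & !is.na(profiles$r)]
    if (length(rs) >= 2L && stats::sd(rs) > 0) {
      tt <- stats::t.test(rs, mu = 0)
      data.frame(direction = d, n = length(rs), mean_r = mean(rs),
                 sd_r = stats::sd(rs), t = unname(tt$statistic),
                 p = tt$p.value, tested = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(direction = d, n = length(rs),
                 mean_r = if (length(rs)) mean(rs) else NA_real_,
                 sd_r = NA_real_, t = NA_real_, p = NA_real_, tested = FALSE,
                 stringsAsFactors = FALSE)
    }
  }))

  msi_by_type <- do.call(rbind, lapply(dirs, function(d) {
    do.call(rbind, lapply(types, function(ty) {
      ms <- profiles$msi[profiles$direction == d & profiles$type == ty &
                           !is.na(profiles$msi)]
      if (length(ms) >= 2L && stats::sd(ms) > 0) {
        tt <- stats::t.test(ms, mu = 0)
        data.frame(direction = d, type = ty, n = length(ms),
                   mean_msi = mean(ms), p = tt$p.value, tested = TRUE,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(direction = d, type = ty, n = length(ms),
                   mean_msi = if (length(ms)) mean(ms) else NA_real_,
                   p = NA_real_, tested = FALSE, stringsAsFactors = FALSE)
      }
    }))
  }))

  list(type_fractions = type_fractions, r_tests = r_tests,
       msi_by_type = msi_by_type)
}
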