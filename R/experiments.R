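#' Calibration and recovery experiments
#'
#' Self-contained simulation experiments that exercise the full pipeline under
#' known ground truth. They back the package's validation suite and the
#' `analysis/` drivers. Problem sizes are the documented study conditions; see
#' the methods vignette for how each was chosen.
#'
#' @name experiments
NULL

#' Generate a session trimmed to fixed neural-trial counts
#'
#' Generates behavior under task defaults and trims the neural-filtered set to
#' exactly `n_per_dir` trials per movement direction (or per direction x
#' modality cell when `per_modality = TRUE`), doubling the raw trial count
#' until the quota is met. This pins the trial budget of simulation
#' experiments regardless of catch/error/correction attrition.
#'
#' @param n_per_dir neural-filtered trials per direction (or per cell).
#' @param seed master seed.
#' @param per_modality balance over modalities as well.
#' @return a neural-filtered `trial_table`.
#' @export
neural_session_trials <- function(n_per_dir, seed, per_modality = FALSE) {
  need <- if (per_modality) n_per_dir * 8L else n_per_dir * 4L
  n_raw <- max(400L, need * 2L)
  repeat {
    tr <- generate_behavior(task_config(n_trials = n_raw,
                                        seed = derive_seed(seed, "beh")))
    neural <- filter_trials(tr, "neural")
    dir <- movement_direction(neural$choice_side, "left")
    sel <- if (per_modality) {
      do.call(rbind, lapply(c("contra", "ipsi"), function(d)
        do.call(rbind, lapply(c("V", "A", "AV"), function(m)
          utils::head(neural[dir == d & neural$modality == m, ], n_per_dir)))))
    } else {
      rbind(utils::head(neural[dir == "contra", ], n_per_dir),
            utils::head(neural[dir == "ipsi", ], n_per_dir))
    }
    target <- if (per_modality) n_per_dir * 6L else n_per_dir * 2L
    if (nrow(sel) == target) return(sel)
    n_raw <- n_raw * 2L
  }
}

#' @describeIn experiments Neuron-type recovery: a population of
#'   `n_per_type` units per movement-related class (premovement amplitude
#'   +/-8 sp/s on a 10 sp/s baseline, RT coupling sized for |r| ~ 0.3) is
#'   simulated over `n_per_dir` neural-filtered trials per direction, profiled
#'   end-to-end, and scored against the generating labels among
#'   representative-flagged unit-directions.
#' @param seed master seed.
#' @param n_per_type units per class.
#' @param n_per_dir neural-filtered trials per direction.
#' @param n_perm permutations per index test.
#' @return list: `accuracy` (among representative rows), `n_representative`,
#'   `profiles`.
#' @export
experiment_type_recovery <- function(seed, n_per_type = 10L,
                                     n_per_dir = 200L, n_perm = 500L) {
  sel <- neural_session_trials(n_per_dir, seed)
  pop <- typed_population(n_per_type = n_per_type)
  units <- generate_spike_trains(sel, pop, seed = derive_seed(seed, "spk"))
  profiles <- do.call(rbind, lapply(units, function(u) {
    unit_profile(u, sel, n_perm = n_perm,
                 seed = derive_seed(seed, paste0("prof_", u$unit_id)))
  }))
  rep_rows <- profiles[profiles$representative, ]
  list(accuracy = mean(rep_rows$type == rep_rows$generated_type),
       n_representative = nrow(rep_rows),
       profiles = profiles)
}

#' @describeIn experiments MSI sign recovery: populations of premovement-
#'   activated units with `av_modulation_factor` 1.5 (enhanced) and 0.6
#'   (depressed) and no RT coupling (so the AV factor is the only AV effect on
#'   the ramp), 200 trials per modality per direction; scores the fraction of
#'   units whose contraversive premovement MSI carries the generating sign.
#' @param n_units units per factor group.
#' @param n_per_cell trials per direction x modality cell.
#' @return list: `frac_correct_enhanced`, `frac_correct_depressed`.
#' @export
experiment_msi_signs <- function(seed, n_units = 20L, n_per_cell = 200L) {
  sel <- neural_session_trials(n_per_cell, seed, per_modality = TRUE)
  dir <- movement_direction(sel$choice_side, "left")
  frac <- vapply(c(1.5, 0.6), function(fac) {
    pop <- lapply(seq_len(n_units), function(i) {
      neuron_params(unit_id = i, premove_amp_sp_s = 8, rt_coupling_beta = 0,
                    av_modulation_factor = fac, generated_type_label = "2")
    })
    units <- generate_spike_trains(sel, pop,
                                   seed = derive_seed(seed, paste0("fac", fac)))
    signs <- vapply(units, function(u) {
      rates <- epoch_rate(u, sel, "withdrawal", c(-100, 0))
      m <- vapply(c("AV", "V", "A"), function(mod) {
        mean(rates[sel$modality == mod & dir == "contra"])
      }, numeric(1))
      sign(msi(m[1], m[2], m[3])$msi)
    }, numeric(1))
    mean(signs == sign(fac - 1))
  }, numeric(1))
  list(frac_correct_enhanced = frac[1], frac_correct_depressed = frac[2])
}

#' @describeIn experiments Spike-detection fidelity: 500 spikes at the
#'   canonical 10 sp/s baseline embedded in a 50-s synthetic tetrode trace at
#'   SNR 10 (trough amplitude 100 uV, noise SD 10 uV); detection events are
#'   matched to ground truth within half a waveform span.
#' @return list: `recall`, `precision`, `n_true`, `n_detected`.
#' @export
experiment_detection <- function(seed) {
  st <- local_seed(derive_seed(seed, "train"), {
    tr <- cumsum(stats::rexp(560, 10) * 1000 + 3)
    tr[tr < 50e3 - 5 & tr > 5]
  })
  u <- structure(list(unit_id = 1L, spike_times_ms = st, ground_truth = NULL),
                 class = "unit_spikes")
  wb <- synthesize_wideband(u, duration_ms = 50e3, amplitude_uv = 100,
                            noise_sd_uv = 10,
                            seed = derive_seed(seed, "noise"))
  cfg <- detection_config()
  ev <- detect_spikes(bandpass(wb$trace, cfg), cfg)
  tol <- cfg$waveform_samples / 2
  recall <- mean(vapply(wb$spike_index,
                        function(i) any(abs(ev - i) <= tol), logical(1)))
  precision <- mean(vapply(ev, function(e) any(abs(wb$spike_index - e) <= tol),
                           logical(1)))
  list(recall = recall, precision = precision,
       n_true = length(wb$spike_index), n_detected = length(ev))
}

#' @describeIn experiments Permutation-test calibration under the null: both
#'   groups Poisson(10) with 20 trials each, 500 permutations, `n_rep`
#'   replicates; returns the rejection rate at alpha = 0.05.
#' @param n_rep replicates.
#' @return rejection rate (scalar).
#' @export
experiment_perm_calibration <- function(seed, n_rep = 1000L) {
  local_seed(derive_seed(seed, "perm_null"), {
    mean(vapply(seq_len(n_rep), function(k) {
      roc_permutation_test(stats::rpois(20, 10), stats::rpois(20, 10),
                           n_perm = 500)$p_value < 0.05
    }, logical(1)))
  })
}

#' @describeIn experiments Behavioral ANOVA calibration: 43 sessions of
#'   per-modality RT means (44 trials per modality per session drawn through
#'   [sample_rt()]). Power arm: 60-ms AV facilitation with ~90-ms SDs, 100
#'   replicate experiments scored for both Tukey contrasts AV < V and AV < A.
#'   Null arm: zero modality effect, `n_null` replicate ANOVAs scored at
#'   alpha = 0.05.
#' @param n_power,n_null replicate counts for the two arms.
#' @return list: `power`, `type_i_rate`.
#' @export
experiment_rt_anova_calibration <- function(seed, n_power = 100L,
                                            n_null = 1000L) {
  sim_means <- function(means, sds, n_per_mod = 44L) {
    do.call(rbind, lapply(1:43, function(s) {
      do.call(rbind, lapply(names(means), function(m) {
        data.frame(session_id = paste0("s", s), modality = m,
                   mean_rt = mean(sample_rt(n_per_mod, means[[m]], sds[[m]])),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  av_contrasts_hit <- function(res) {
    tk <- res$tukey
    av_a <- tk[tk$comparison %in% c("AV-A", "A-AV"), ]
    av_v <- tk[tk$comparison %in% c("AV-V", "V-AV"), ]
    sgn <- function(row, first) if (row$comparison == first) row$diff < 0 else row$diff > 0
    av_a$p_adj < 0.05 && av_v$p_adj < 0.05 &&
      sgn(av_a, "AV-A") && sgn(av_v, "AV-V")
  }
  power <- local_seed(derive_seed(seed, "anova_power"), {
    mean(vapply(seq_len(n_power), function(k) {
      d <- sim_means(c(V = 390, A = 390, AV = 330), c(V = 90, A = 90, AV = 90))
      av_contrasts_hit(rt_anova(d))
    }, logical(1)))
  })
  type_i <- local_seed(derive_seed(seed, "anova_null"), {
    mean(vapply(seq_len(n_null), function(k) {
      d <- sim_means(c(V = 390, A = 390, AV = 390), c(V = 90, A = 90, AV = 90))
      rt_anova(d)$p < 0.05
    }, logical(1)))
  })
  list(power = power, type_i_rate = type_i)
}
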