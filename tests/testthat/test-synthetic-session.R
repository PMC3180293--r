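test_that("behavioral generator reproduces the task structure", {
  cfg <- task_config(n_trials = 6000L, seed = 42L)
  tr <- generate_behavior(cfg)

  expect_equal(nrow(tr), 6000L)

  # catch fraction within 3 binomial SDs of 16.7%
  p_catch <- mean(tr$modality == "catch")
  band <- 3 * sqrt(0.167 * 0.833 / 6000)
  expect_lt(abs(p_catch - 0.167), band)

  # catch trials have no cue and no stimulus side
  catch <- tr[tr$modality == "catch", ]
  expect_true(all(is.na(catch$cue_on_ms)))
  expect_true(all(catch$stimulus_side == "none"))

  # modalities equiprobable among non-catch trials that were freely scheduled
  sched <- tr[tr$modality != "catch" & !tr$is_correction_trial, ]
  tab <- table(sched$modality)
  expect_true(all(abs(tab / sum(tab) - 1 / 3) <
                    3 * sqrt((1 / 3) * (2 / 3) / nrow(sched))))

  # foreperiods inside [400, 800) for cued trials
  fp <- tr$cue_on_ms - tr$poke_in_ms
  expect_true(all(fp[!is.na(fp)] >= 400 & fp[!is.na(fp)] < 800))

  # rt = withdrawal - cue_on, nonnegative
  rt_chk <- tr$withdrawal_ms - tr$cue_on_ms
  expect_equal(rt_chk[!is.na(rt_chk)], tr$rt_ms[!is.na(tr$rt_ms)])
  expect_true(all(tr$rt_ms[!is.na(tr$rt_ms)] >= 0))

  # error trials move opposite to the stimulus
  err <- tr[!tr$correct & tr$modality != "catch", ]
  expect_true(all(err$choice_side != err$stimulus_side))
  expect_true(all(err$choice_side %in% c("left", "right")))
})

test_that("per-modality RT means match the configured shifted log-normal law", {
  cfg <- task_config(n_trials = 6000L, seed = 7L)
  tr <- generate_behavior(cfg)
  for (m in c("V", "A", "AV")) {
    x <- tr$rt_ms[tr$modality == m]
    sem <- cfg$rt_sd_ms[[m]] / sqrt(length(x))
    expect_lt(abs(mean(x) - cfg$rt_mean_ms[[m]]), 3 * sem)
  }
  # the sampler itself hits mean and SD at large n
  set.seed(1)
  x <- sample_rt(2e5, 386.3, 98.7)
  expect_equal(mean(x), 386.3, tolerance = 0.005)
  expect_equal(sd(x), 98.7, tolerance = 0.01)
  expect_true(all(x > 100))
})

test_that("empty and invalid configurations are handled", {
  tr <- generate_behavior(task_config(n_trials = 0L))
  expect_equal(nrow(tr), 0L)
  expect_error(task_config(rt_mean_ms = c(V = NaN, A = 394.9, AV = 322.4)),
               "non-finite")
  expect_error(task_config(foreperiod_range_ms = c(800, 400)))
  expect_error(task_config(rt_mean_ms = c(V = 386, A = 395, X = 322)),
               "named over")
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- task_config(n_trials = 300L, seed = 5L)
  expect_identical(generate_behavior(cfg), generate_behavior(cfg))
  tr <- generate_behavior(cfg)
  pop <- typed_population(n_per_type = 1L)
  u1 <- generate_spike_trains(tr, pop, seed = 9L)
  u2 <- generate_spike_trains(tr, pop, seed = 9L)
  expect_identical(lapply(u1, `[[`, "spike_times_ms"),
                   lapply(u2, `[[`, "spike_times_ms"))
})

test_that("trial rate function composes baseline, sensory and ramp terms", {
  tr <- single_trial(cue_on = 1000, rt = 300, modality = "V")
  flat <- neuron_params(baseline_rate_sp_s = 10, premove_amp_sp_s = 0,
                        sensory_amp_V_sp_s = 0, sensory_amp_A_sp_s = 0)
  f <- trial_rate_function(tr, flat, median_rt = 300)
  expect_equal(f(seq(500, 1600, by = 10)), rep(10, 111))

  # zero ipsi gain: ipsiversive trials carry baseline + sensory only
  tri <- single_trial(choice = "left") # left hemisphere -> ipsi
  p <- neuron_params(baseline_rate_sp_s = 10, premove_amp_sp_s = 8,
                     direction_gain_ipsi = 0, sensory_amp_V_sp_s = 5)
  fi <- trial_rate_function(tri, p, median_rt = 300)
  sens <- 10 + 5 * exp(-(seq(900, 1300) - 1040)^2 / (2 * 15^2)) *
    (seq(900, 1300) >= 1000)
  expect_equal(fi(seq(900, 1300)), sens)

  # negative RT coupling: ramp amplitude strictly decreasing in RT
  p2 <- neuron_params(premove_amp_sp_s = 8, rt_coupling_beta = -0.05)
  amps <- vapply(seq(200, 600, by = 50), function(rt) {
    trx <- single_trial(rt = rt)
    fx <- trial_rate_function(trx, p2, median_rt = 400)
    fx(trx$withdrawal_ms - 1e-9) # ramp peak
  }, numeric(1))
  expect_true(all(diff(amps) < 0))

  # rates are clamped at zero
  p3 <- neuron_params(baseline_rate_sp_s = 2, premove_amp_sp_s = -30)
  f3 <- trial_rate_function(single_trial(), p3, median_rt = 300)
  expect_true(all(f3(seq(900, 1400, by = 1)) >= 0))
})

test_that("thinned spike trains are Poisson with the requested rate", {
  # constant-rate neuron: counts match Poisson mean/variance over long exposure
  cfg <- task_config(n_trials = 400L, seed = 3L, catch_fraction = 0,
                     error_rate = 0)
  tr <- generate_behavior(cfg)
  p <- neuron_params(baseline_rate_sp_s = 10, premove_amp_sp_s = 0,
                     sensory_amp_V_sp_s = 0)
  u <- generate_spike_trains(tr, p = list(p), seed = 21L)[[1]]
  expect_true(!is.unsorted(u$spike_times_ms, strictly = TRUE))
  expect_true(all(u$spike_times_ms >= 0))

  # baseline-epoch counts over 400 trials: mean within 3 SEM of 10 sp/s
  r <- epoch_rate(u, tr, "cue_on", c(-100, 0))
  expect_lt(abs(mean(r) - 10), 3 * sqrt(10 / 0.1) / sqrt(length(r)))

  # Poisson dispersion of epoch counts (variance/mean near 1)
  counts <- r * 0.1
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)

  # zero-rate neuron emits nothing
  z <- neuron_params(baseline_rate_sp_s = 0, premove_amp_sp_s = 0,
                     sensory_amp_V_sp_s = 0)
  expect_length(generate_spike_trains(tr, list(z), seed = 1L)[[1]]$spike_times_ms, 0)
})

test_that("wideband synthesis is linear and has the requested noise floor", {
  tpl <- spike_template()
  expect_length(tpl, 32L)
  expect_equal(which.min(tpl), 10L)
  expect_equal(min(tpl), -1)

  # noiseless single spike: trace equals the scaled template at that span
  u <- as_unit(10) # 10 ms -> sample 251
  wb <- synthesize_wideband(u, duration_ms = 40, amplitude_uv = 80,
                            channel_gains = c(1, 0.5), noise_sd_uv = 0)
  ctr <- round(10 * 25) + 1
  span <- (ctr - 9):(ctr + 22)
  expect_equal(wb$trace[1, span], 80 * tpl)
  expect_equal(wb$trace[2, span], 40 * tpl)
  expect_true(all(wb$trace[, -span] == 0))

  # pure noise: sample SD within 5% for a 10-s trace
  wb0 <- synthesize_wideband(as_unit(numeric(0)), duration_ms = 10e3,
                             noise_sd_uv = 12, seed = 4L)
  expect_lt(abs(sd(wb0$trace[1, ]) - 12) / 12, 0.05)

  # two units at disjoint times superpose linearly
  u1 <- as_unit(5, unit_id = 1L)
  u2 <- as_unit(20, unit_id = 2L)
  both <- synthesize_wideband(list(u1, u2), duration_ms = 40, noise_sd_uv = 0)
  one <- synthesize_wideband(u1, duration_ms = 40, noise_sd_uv = 0)
  two <- synthesize_wideband(u2, duration_ms = 40, noise_sd_uv = 0)
  expect_equal(both$trace, one$trace + two$trace)
})
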