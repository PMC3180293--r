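test_that("band-pass filter has the designed pass and stop behaviour", {
  cfg <- detection_config()
  fs <- cfg$fs_hz
  t <- seq(0, 1, by = 1 / fs)

  # 2 kHz sinusoid (mid-band) passes within 5%
  x <- sin(2 * pi * 2000 * t)
  y <- bandpass(x, cfg)
  core <- seq(2000, length(y) - 2000) # skip filter edge transients
  expect_lt(abs(max(abs(y[core])) - 1), 0.05)

  # 100 Hz sinusoid attenuated by >= 20 dB
  x_lo <- sin(2 * pi * 100 * t)
  y_lo <- bandpass(x_lo, cfg)
  expect_lt(max(abs(y_lo[core])), 0.1)

  # zeros in, zeros out
  expect_equal(bandpass(rep(0, 1000), cfg), rep(0, 1000))

  # Nyquist guard
  expect_error(detection_config(bandpass_hz = c(800, 20000)), "Nyquist")
})

test_that("RMS-power detection recovers embedded spikes and behaves at limits", {
  set.seed(11)
  st <- poisson_train_ms(10, 20e3)
  u <- as_unit(st)
  wb <- synthesize_wideband(u, duration_ms = 20e3, amplitude_uv = 100,
                            noise_sd_uv = 10, seed = 5L)
  cfg <- detection_config()
  filt <- bandpass(wb$trace, cfg)
  ev <- detect_spikes(filt, cfg)

  tol <- cfg$waveform_samples / 2
  recall <- mean(vapply(wb$spike_index,
                        function(i) any(abs(ev - i) <= tol), logical(1)))
  precision <- mean(vapply(ev,
                           function(e) any(abs(wb$spike_index - e) <= tol),
                           logical(1)))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)

  # zero trace: no events; absurd threshold: no events
  expect_length(detect_spikes(rep(0, 10000), cfg), 0L)
  hard <- detection_config(threshold_k = 1e9)
  expect_length(detect_spikes(filt, hard), 0L)

  # raising the threshold never detects more
  ks <- c(3, 5, 8, 12)
  counts <- vapply(ks, function(k) {
    length(detect_spikes(filt, detection_config(threshold_k = k)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is translation-equivariant away from trace edges", {
  set.seed(3)
  st <- poisson_train_ms(10, 5e3)
  wb <- synthesize_wideband(as_unit(st), duration_ms = 5e3,
                            amplitude_uv = 120, noise_sd_uv = 10, seed = 2L)
  cfg <- detection_config()
  filt <- bandpass(wb$trace, cfg)
  k <- 1000L
  n <- ncol(filt)
  shifted <- filt[, c((n - k + 1):n, 1:(n - k)), drop = FALSE]
  ev <- detect_spikes(filt, cfg)
  ev_s <- detect_spikes(shifted, cfg)
  core <- ev[ev > 2 * k & ev < n - 2 * k]
  expect_true(all((core + k) %in% ev_s))
})

test_that("waveform extraction aligns troughs and drops edge events", {
  tpl <- spike_template()
  wb <- synthesize_wideband(as_unit(c(0.1, 10)), duration_ms = 40,
                            amplitude_uv = 60, noise_sd_uv = 0)
  cfg <- detection_config()
  ctr2 <- round(10 * 25) + 1
  # event near sample 3 is undroppable; in-bounds event recovered exactly
  w <- extract_waveforms(wb$trace, c(3L, ctr2), cfg)
  expect_equal(attr(w, "n_dropped"), 1L)
  expect_equal(dim(w), c(1L, 32L, 4L))
  expect_equal(w[1, , 1], 60 * tpl)

  # row count equals in-bounds event count
  ev <- as.integer(seq(100, 900, by = 100))
  w2 <- extract_waveforms(wb$trace, ev, cfg)
  expect_equal(dim(w2)[1], length(ev))
})

test_that("refractory violation fraction counts short ISIs", {
  expect_equal(refractory_violation_fraction(seq(0, 1000, by = 10)), 0)
  st <- sort(c(seq(0, 990, by = 10), 991)) # 101 spikes, exactly one ISI = 1 ms
  expect_equal(refractory_violation_fraction(st), 0.01)
  expect_warning(out <- refractory_violation_fraction(5), "fewer than 2")
  expect_equal(out, 0)

  # exponential ISI law: fraction ~ 1 - exp(-rate * refractory)
  set.seed(8)
  isi <- rexp(1e4, 20) # seconds at 20 sp/s
  st2 <- cumsum(isi) * 1000
  expected <- 1 - exp(-20 * 0.0015)
  frac <- refractory_violation_fraction(st2)
  expect_lt(abs(frac - expected),
            3 * sqrt(expected * (1 - expected) / 1e4))
})

test_that("isolation distance matches its Mahalanobis definition", {
  set.seed(15)
  # non-cluster spikes at the cluster center -> distance 0
  cl <- matrix(rnorm(200 * 2), ncol = 2)
  center <- matrix(colMeans(cl), nrow = 5, ncol = 2, byrow = TRUE)
  expect_equal(as.numeric(isolation_distance(cl, center)), 0)

  # well-separated isotropic clusters: large distance, agrees with brute force
  a <- matrix(rnorm(500 * 2), ncol = 2)
  b <- matrix(rnorm(500 * 2), ncol = 2)
  b[, 1] <- b[, 1] + 10
  id <- isolation_distance(a, b)
  expect_gt(id, 20)
  md <- mahalanobis(b, colMeans(a), cov(a))
  expect_equal(id, sort(md)[nrow(a)])

  # same-distribution cluster and noise: below the chi-square 99th percentile
  hits <- vapply(1:100, function(k) {
    cl2 <- matrix(rnorm(50 * 2), ncol = 2)
    oth <- matrix(rnorm(500 * 2), ncol = 2)
    isolation_distance(cl2, oth) < qchisq(0.99, df = 2)
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # fewer non-cluster spikes than cluster size: capped at the maximum
  small <- matrix(rnorm(10 * 2, mean = 5), ncol = 2)
  capped <- isolation_distance(a, small)
  expect_true(isTRUE(attr(capped, "capped")))
  expect_equal(as.numeric(capped), max(mahalanobis(small, colMeans(a), cov(a))))

  # degenerate covariance is refused
  flat <- cbind(rnorm(50), 0)
  expect_error(isolation_distance(flat, matrix(rnorm(10 * 2), ncol = 2)),
               "singular")
})

test_that("unit acceptance combines both published quality criteria", {
  expect_true(accept_unit(0.005, 25))
  expect_false(accept_unit(0.02, 25))
  expect_false(accept_unit(0.005, 15))
  expect_false(accept_unit(0.01, 20))
})

test_that("waveform features have the documented layout", {
  set.seed(2)
  wfs <- array(rnorm(20 * 32 * 4), dim = c(20, 32, 4))
  f <- waveform_features(wfs)
  expect_equal(dim(f), c(20L, 20L)) # 5 features x 4 channels
  expect_equal(f[, 1], rowSums(wfs[, , 1]^2))
})
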