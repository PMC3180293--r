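test_that("roc_area equals brute-force pair counting, exhaustively with ties", {
  # every multiset pair of sizes up to 4 from a 3-value grid (ties included)
  grid_vals <- c(0, 1, 2)
  multisets <- unlist(lapply(1:4, function(k) {
    combn(length(grid_vals) + k - 1, k, function(ix) {
      list(grid_vals[ix - seq_len(k) + 1])
    }, simplify = FALSE)
  }), recursive = FALSE)
  multisets <- lapply(multisets, `[[`, 1)
  for (a in multisets) for (b in multisets) {
    expect_identical(roc_area(a, b), brute_roc_area(a, b))
  }

  # larger random instances with heavy ties
  set.seed(77)
  for (k in 1:200) {
    a <- sample(0:3, sample(1:8, 1), replace = TRUE)
    b <- sample(0:3, sample(1:8, 1), replace = TRUE)
    expect_equal(roc_area(a, b), brute_roc_area(a, b))
  }
})

test_that("roc index has the documented fixed points and symmetries", {
  expect_equal(roc_area(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_area(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(roc_area(c(2, 4), c(1, 3)), 0.75)
  expect_equal(roc_index(c(2, 4), c(1, 3)), 0.5)
  expect_equal(roc_index(c(7, 7), c(7, 7)), 0)
  expect_error(roc_area(numeric(0), 1), "nonempty")

  set.seed(5)
  for (k in 1:50) {
    a <- rpois(sample(2:10, 1), 8)
    b <- rpois(sample(2:10, 1), 8)
    # complementarity (to rounding) and bit-exact antisymmetry, with ties
    expect_equal(roc_area(a, b) + roc_area(b, a), 1, tolerance = 1e-14)
    expect_identical(roc_index(a, b), -roc_index(b, a))
    # invariance under strictly monotone transforms
    f <- function(x) exp(x / 3) + x
    expect_identical(roc_index(a, b), roc_index(f(a), f(b)))
  }
})

test_that("permutation test is reproducible, bounded below, and calibrated", {
  # identical constant samples: every permuted index equals the observed one
  expect_equal(roc_permutation_test(rep(3, 5), rep(3, 5), seed = 1)$p_value, 1)

  # minimum attainable p at 500 permutations is 1/501
  res <- roc_permutation_test(101:120, 1:20, n_perm = 500, seed = 2)
  expect_equal(res$p_value, 1 / 501)
  expect_equal(res$index, 1)

  # reproducible under a fixed seed, and n_perm must be positive
  r1 <- roc_permutation_test(rpois(15, 10), rpois(15, 10), seed = 7)
  r2 <- roc_permutation_test(rpois(15, 10), rpois(15, 10), seed = 7)
  expect_error(roc_permutation_test(1:3, 4:6, n_perm = 0), "n_perm")

  # null calibration: rejection rate close to alpha (reduced replicate count
  # here; the full-size run lives with the acceptance checks)
  set.seed(99)
  rej <- vapply(1:300, function(k) {
    roc_permutation_test(rpois(20, 10), rpois(20, 10),
                         n_perm = 200)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("sliding-window time course finds condition differences where present", {
  seed <- 23L
  sess <- neural_session(100, seed = seed)
  dirs <- movement_direction(sess$choice_side, "left")
  # contra-preferring neuron: gain ratio 2
  p <- neuron_params(premove_amp_sp_s = 10, rt_coupling_beta = 0,
                     direction_gain_contra = 2, direction_gain_ipsi = 1)
  u <- generate_spike_trains(sess, list(p), seed = derive_seed(seed, "u"))[[1]]
  spec <- alignment_spec("withdrawal", c(-300, 100), 15, 1)
  s_contra <- compute_sdf(u, sess[dirs == "contra", ], spec)
  s_ipsi <- compute_sdf(u, sess[dirs == "ipsi", ], spec)
  tc <- roc_timecourse(s_contra, s_ipsi, n_perm = 200,
                       seed = derive_seed(seed, "tc"))

  # geometry: centers fully inside the grid, 20-ms steps
  expect_equal(tc$window_centers_ms[1], -250)
  expect_equal(diff(tc$window_centers_ms), rep(20, length(tc$window_centers_ms) - 1))
  expect_lte(max(tc$window_centers_ms) + 50, 100)

  # significant positive windows overlap the premovement epoch
  pm <- tc$window_centers_ms >= -100 & tc$window_centers_ms <= 0
  expect_true(any(tc$significant[pm] & tc$index[pm] > 0))

  # identical trial sets: all indices 0
  tc0 <- roc_timecourse(s_contra, s_contra, n_perm = 100, seed = 1L)
  expect_true(all(tc0$index == 0))
  expect_false(any(tc0$significant))

  # step = width tiles the span without overlap
  tc_tile <- roc_timecourse(s_contra, s_ipsi, width_ms = 100, step_ms = 100,
                            n_perm = 10, seed = 1L)
  expect_equal(length(tc_tile$window_centers_ms), floor(400 / 100))

  expect_error(roc_timecourse(
    compute_sdf(u, sess[1, ], alignment_spec("withdrawal", c(-30, 30))),
    compute_sdf(u, sess[2, ], alignment_spec("withdrawal", c(-30, 30))),
    width_ms = 100), "shorter")
})

test_that("center of mass averages significant positive windows only", {
  tc <- structure(list(
    window_centers_ms = c(-20, 40, 60),
    index = c(0.5, 0.5, -0.8),
    significant = c(TRUE, FALSE, TRUE)
  ), class = "roc_timecourse")
  expect_equal(as.numeric(center_of_mass(tc)), -20)

  tc$significant <- c(TRUE, TRUE, TRUE)
  # two equal positive indices at -20 and +60: midpoint
  tc$window_centers_ms <- c(-20, 60, 100)
  tc$index <- c(0.5, 0.5, -0.8)
  expect_equal(as.numeric(center_of_mass(tc)), 20)

  tc$index <- c(-0.5, -0.5, -0.8)
  com <- center_of_mass(tc)
  expect_true(is.na(com))
  expect_false(attr(com, "defined"))
})

test_that("premovement and direction indices wire the right epochs", {
  seed <- 31L
  sess <- neural_session(80, seed = seed)
  p <- neuron_params(premove_amp_sp_s = 12, rt_coupling_beta = 0)
  u <- generate_spike_trains(sess, list(p), seed = derive_seed(seed, "u"))[[1]]
  pm <- premovement_index(u, sess, n_perm = 200, seed = 3L)
  expect_gt(pm$index, 0)
  expect_lt(pm$p_value, 0.05)

  # suppression flips the sign
  ps <- neuron_params(premove_amp_sp_s = -8, rt_coupling_beta = 0)
  us <- generate_spike_trains(sess, list(ps), seed = derive_seed(seed, "s"))[[1]]
  expect_lt(premovement_index(us, sess, n_perm = 200, seed = 3L)$index, 0)

  # contra-gained neuron: positive direction preference
  pd <- neuron_params(premove_amp_sp_s = 10, rt_coupling_beta = 0,
                      direction_gain_contra = 2, direction_gain_ipsi = 0.5)
  ud <- generate_spike_trains(sess, list(pd), seed = derive_seed(seed, "d"))[[1]]
  dp <- direction_preference(ud, sess, n_perm = 200, seed = 4L)
  expect_gt(dp$index, 0)
  expect_lt(dp$p_value, 0.05)
})

test_that("correct-versus-error preference shares sign for movement-coded units", {
  seed <- 41L
  hits <- vapply(1:30, function(k) {
    tr <- generate_behavior(task_config(n_trials = 260L, error_rate = 0.25,
                                        seed = derive_seed(seed, paste0("b", k))))
    p <- neuron_params(premove_amp_sp_s = 12, rt_coupling_beta = 0,
                       direction_gain_contra = 2.5, direction_gain_ipsi = 0.4)
    u <- generate_spike_trains(tr, list(p),
                               seed = derive_seed(seed, paste0("u", k)))[[1]]
    res <- correct_vs_error_preference(u, tr, n_perm = 100,
                                       seed = derive_seed(seed, paste0("s", k)))
    if (!res$sufficient) return(NA)
    sign(res$index_correct) == sign(res$index_error)
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.9)

  # insufficiency paths
  tr0 <- generate_behavior(task_config(n_trials = 100L, error_rate = 0, seed = 2L))
  u0 <- as_unit(runif(100, 0, max(tr0$withdrawal_ms, na.rm = TRUE)))
  expect_false(correct_vs_error_preference(u0, tr0)$sufficient)
})
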