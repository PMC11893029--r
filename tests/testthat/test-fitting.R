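test_that("dictionary matching identifies its own rows and is scale
           invariant", {
  sq <- seq_params() # full-length train: entries are distinguishable
  dict <- build_dictionary(parameter_grid(n_per_axis = 6L), sq)
  row <- 123L
  tc <- dict$x[row, ]
  hit <- dictionary_match(tc, dict)
  expect_equal(attr(hit, "match_index"), row)
  expect_equal(hit$delta_t, dict$grid$delta_t[row])
  expect_equal(hit$amplitude, 1, tolerance = 1e-10)
  hit3 <- dictionary_match(3 * tc, dict)
  expect_equal(attr(hit3, "match_index"), row)
  expect_equal(hit3$amplitude, 3, tolerance = 1e-10)
  expect_null(dictionary_match(rep(0, ncol(dict$x)), dict))
})

test_that("dictionary matching agrees with an exhaustive correlation
           search for off-grid curves", {
  sc <- small_scene()
  kp <- kinetic_params(0.77, 6.3, 0.21, amplitude = 1.4)
  tc <- simulate_timecourse(kp, sc$seq)$values
  hit <- dictionary_match(tc, sc$dict)
  # brute force over every entry
  best <- which.max(vapply(seq_len(nrow(sc$dict$x)), function(r) {
    x <- sc$dict$x[r, ]
    sum(x * tc) / sqrt(sum(x^2) * sum(tc^2))
  }, numeric(1)))
  expect_equal(attr(hit, "match_index"), best)
})

test_that("refinement at the truth stays at the truth with near-zero
           residual", {
  sq <- seq_params()
  kp <- kinetic_params(0.6, 4, 0.25, amplitude = 1.2)
  tc <- simulate_timecourse(kp, sq)$values
  fit <- refine_fit(tc, kp, sq)
  expect_equal(fit$delta_t, kp$delta_t, tolerance = 1e-6)
  expect_equal(fit$sharpness, kp$sharpness, tolerance = 1e-5)
  expect_equal(fit$time_to_peak, kp$time_to_peak, tolerance = 1e-6)
  expect_lt(attr(fit, "residual_nrmse"), 1e-8)
})

test_that("dictionary-match initialization plus refinement recovers
           off-grid parameters within 1%", {
  sq <- seq_params()
  sc_dict <- build_dictionary(parameter_grid(n_per_axis = 10L), sq)
  cases <- data.frame(
    delta_t = c(0.33, 0.91, 1.47),
    sharpness = c(7.2, 2.6, 11.8),
    time_to_peak = c(0.17, 0.42, 0.09),
    amplitude = c(1.0, 2.1, 0.7)
  )
  for (r in seq_len(nrow(cases))) {
    kp <- kinetic_params(cases$delta_t[r], cases$sharpness[r],
                         cases$time_to_peak[r], cases$amplitude[r])
    tc <- simulate_timecourse(kp, sq)$values
    init <- dictionary_match(tc, sc_dict)
    fit <- refine_fit(tc, init, sq)
    expect_lt(abs(fit$delta_t - kp$delta_t) / kp$delta_t, 0.01)
    expect_lt(abs(fit$sharpness - kp$sharpness) / kp$sharpness, 0.01)
    expect_lt(abs(fit$time_to_peak - kp$time_to_peak) / kp$time_to_peak,
              0.01)
    expect_lt(abs(fit$amplitude - kp$amplitude) / kp$amplitude, 0.01)
  }
})

test_that("noiseless self-consistency holds across random in-bounds
           parameter draws", {
  sq <- seq_params()
  dict <- build_dictionary(parameter_grid(n_per_axis = 8L), sq)
  set.seed(31)
  n_ok <- 0L
  for (rep in 1:50) {
    kp <- kinetic_params(runif(1, 0.15, 1.2), runif(1, 1.5, 15),
                         runif(1, 0.03, 0.45), amplitude = runif(1, 0.5, 2))
    tc <- simulate_timecourse(kp, sq)$values
    if (max(tc) == 0) next
    init <- dictionary_match(tc, dict)
    fit <- refine_fit(tc, init, sq)
    rel <- c(abs(fit$delta_t - kp$delta_t) / kp$delta_t,
             abs(fit$sharpness - kp$sharpness) / kp$sharpness,
             abs(fit$time_to_peak - kp$time_to_peak) / kp$time_to_peak,
             abs(fit$amplitude - kp$amplitude) / kp$amplitude)
    expect_lt(max(rel), 0.01)
    n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 45L)
})

test_that("refined fits never have larger residual than their
           dictionary-match initialization", {
  sq <- short_seq()
  dict <- build_dictionary(parameter_grid(n_per_axis = 6L), sq)
  set.seed(32)
  for (rep in 1:5) {
    kp <- kinetic_params(runif(1, 0.2, 1.0), runif(1, 2, 12),
                         runif(1, 0.05, 0.4))
    tc <- simulate_timecourse(kp, sq)$values
    init <- dictionary_match(tc, dict)
    init_resid <- sqrt(mean((simulate_timecourse(init, sq)$values - tc)^2)) /
      sqrt(mean(tc^2))
    fit <- refine_fit(tc, init, sq)
    expect_lte(attr(fit, "residual_nrmse"), init_resid + 1e-12)
  }
})

test_that("volume fitting masks empty voxels and recovers the vessel
           ramps on ground-truth data", {
  sq <- seq_params()
  ph <- vessel_phantom(9L, delta_t_range = c(0.2, 0.9))
  ser <- phantom_series(ph, sq)
  dict <- build_dictionary(parameter_grid(n_per_axis = 8L), sq)
  maps <- fit_volume(ser, sq, dict, mask = ph$voxels)
  tab <- vessel_fit_table(maps, ph)
  expect_true(all(tab$mask))
  # monotone transit-time ramp, allowing end-voxel exceptions
  dtv <- tab$delta_t
  violations <- sum(diff(dtv) < 0)
  expect_lte(violations, 2L)
  expect_lt(mean(abs(dtv - tab$true_delta_t) / tab$true_delta_t), 0.02)
  # empty input gives empty maps
  zero <- array(0i, dim = c(9, 9, 9, sq$n_readouts))
  maps0 <- fit_volume(zero, sq, dict)
  expect_equal(sum(maps0$mask), 0L)
  expect_true(all(is.na(maps0$delta_t)))
})

test_that("bin-averaged fitting reproduces parameters from binned
           ground-truth frames", {
  sq <- seq_params()
  kp <- kinetic_params(0.5, 5, 0.2, amplitude = 1.3)
  tc <- simulate_timecourse(kp, sq)$values
  binned <- vapply(seq(1, 144, by = 12), function(f) mean(tc[f:(f + 11)]),
                   numeric(1))
  dict <- build_dictionary(parameter_grid(n_per_axis = 8L), sq)
  init <- dictionary_match(binned, bin_average_dictionary(dict, 12L))
  fit <- refine_fit(binned, init, sq, bin_size = 12L)
  expect_lt(abs(fit$delta_t - kp$delta_t) / kp$delta_t, 0.05)
  expect_lt(attr(fit, "residual_nrmse"), 1e-5)
})
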