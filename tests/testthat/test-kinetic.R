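test_that("quadratic flip schedule hits its endpoints and stated values", {
  sq <- seq_params()
  fa <- quadratic_flip_schedule(sq)
  expect_equal(fa[1], 3)
  expect_equal(fa[144], 12)
  expect_true(all(diff(fa) >= 0))
  # direct evaluation of the quadratic at N = 3
  fa3 <- quadratic_flip_schedule(seq_params(n_readouts = 3L))
  expect_equal(fa3[2], 3 + 9 * 0.25)
  # degenerate constant schedule
  fac <- quadratic_flip_schedule(
    seq_params(flip_min = 5, flip_max = 5, n_readouts = 7L))
  expect_equal(fac, rep(5, 7))
  expect_equal(quadratic_flip_schedule(seq_params(n_readouts = 1L)), 3)
})

test_that("dispersion kernel matches its closed form and support", {
  kp <- kinetic_params(0.5, sharpness = 2, time_to_peak = 0.5)
  expect_equal(gamma_dispersion_kernel(0.5, kp), 2 * exp(-1),
               tolerance = 1e-12)
  expect_equal(gamma_dispersion_kernel(c(-1, 0), kp), c(0, 0))
  expect_error(gamma_dispersion_kernel(NaN, kp), "finite")
})

test_that("dispersion kernel integrates to one and peaks at the
           time-to-peak across the dictionary parameter ranges", {
  for (s in c(1, 5, 20)) {
    for (p in c(0.001, 0.1, 0.5)) {
      kp <- kinetic_params(0, s, p)
      total <- stats::integrate(function(td) gamma_dispersion_kernel(td, kp),
                                0, Inf, rel.tol = 1e-9)$value
      expect_equal(total, 1, tolerance = 1e-6)
      # stationarity: the maximum over a fine grid sits at td = p
      td <- seq(p / 4, 4 * p, length.out = 4001)
      expect_equal(td[which.max(gamma_dispersion_kernel(td, kp))], p,
                   tolerance = 2e-3)
    }
  }
})

test_that("T1 recovery factor is the expected exponential decay", {
  expect_equal(t1_recovery_factor(0, 0, 1.65), 1)
  expect_equal(t1_recovery_factor(0.5, 0.1, 1.65), exp(-0.6 / 1.65))
  td <- seq(0, 3, by = 0.25)
  expect_true(all(diff(t1_recovery_factor(0.3, td, 1.65)) < 0))
})

test_that("RF attenuation counts whole TR intervals and never grows", {
  tr <- 0.0147
  angles <- rep(10, 144)
  expect_equal(rf_attenuation_factor(tr / 2, angles, tr), 1)
  expect_equal(rf_attenuation_factor(3.5 * tr, angles, tr),
               cos(10 * pi / 180)^3, tolerance = 1e-12)
  td <- seq(0, 150 * tr, by = tr / 3)
  fac <- rf_attenuation_factor(td, angles, tr)
  expect_true(all(diff(fac) <= 0))
  # capped at the number of pulses
  expect_equal(rf_attenuation_factor(1000 * tr, angles, tr),
               cos(10 * pi / 180)^144)
  expect_error(rf_attenuation_factor(-0.1, angles, tr), "non-negative")
})

test_that("signal is zero before arrival and scales with amplitude", {
  sq <- seq_params()
  kp <- kinetic_params(1.0, 5, 0.1, amplitude = 2)
  expect_equal(angiographic_signal(0.5, kp, sq, 1L), 0)
  kp0 <- kinetic_params(0.5, 5, 0.1, amplitude = 0)
  t_ex <- excitation_times(sq)[c(1, 50, 144)]
  expect_equal(angiographic_signal(t_ex, kp0, sq, c(1L, 50L, 144L)),
               c(0, 0, 0))
})

test_that("a very sharp kernel acts as a delta at the time-to-peak", {
  sq <- seq_params()
  kp <- kinetic_params(0.3, sharpness = 500, time_to_peak = 0.02)
  t_ex <- excitation_times(sq)
  i <- 10L # t inside (delta_t + p, delta_t + tau): bolus still flowing
  angles <- quadratic_flip_schedule(sq)
  s_val <- angiographic_signal(t_ex[i], kp, sq, i)
  approx_val <- sin(angles[i] * pi / 180) *
    t1_recovery_factor(kp$delta_t, kp$time_to_peak, sq$t1_blood) *
    rf_attenuation_factor(kp$time_to_peak, angles, sq$tr)
  expect_equal(s_val, approx_val, tolerance = 0.02)
})

test_that("analytic timecourse matches dense quadrature on the full
           sequence", {
  sq <- seq_params()
  kp <- kinetic_params(0.25, sharpness = 5, time_to_peak = 0.1)
  tc <- simulate_timecourse(kp, sq)
  oracle <- oracle_timecourse(kp, sq, nodes_per_tr = 400L)
  expect_lt(max(abs(tc$values - oracle)) / max(oracle), 1e-6)
})

test_that("analytic integrator agrees with the quadrature oracle on
           random parameter draws", {
  sq <- short_seq()
  set.seed(42)
  for (rep in 1:100) {
    kp <- kinetic_params(runif(1, 0, 2), runif(1, 1, 20),
                         runif(1, 0.005, 0.5), amplitude = runif(1, 0.5, 2))
    tc <- simulate_timecourse(kp, sq)
    # Richardson-extrapolated midpoint rule: h^4-accurate reference
    oracle <- (4 * oracle_timecourse(kp, sq, nodes_per_tr = 160L) -
                 oracle_timecourse(kp, sq, nodes_per_tr = 80L)) / 3
    denom <- max(oracle)
    if (denom == 0) {
      expect_equal(max(tc$values), 0)
    } else {
      expect_lt(max(abs(tc$values - oracle)) / denom, 1e-6)
    }
  }
})

test_that("timecourses are non-negative, deterministic, and zero when
           blood never arrives", {
  sq <- short_seq()
  kp <- kinetic_params(0.4, 8, 0.2)
  tc1 <- simulate_timecourse(kp, sq)
  tc2 <- simulate_timecourse(kp, sq)
  expect_identical(tc1$values, tc2$values)
  expect_true(all(tc1$values >= 0))
  t_end <- sq$labeling_duration + sq$n_readouts * sq$tr
  late <- kinetic_params(t_end + 0.1, 8, 0.2)
  expect_equal(simulate_timecourse(late, sq)$values, rep(0, sq$n_readouts))
  # zero before arrival
  t_ex <- excitation_times(sq)
  expect_true(all(tc1$values[t_ex <= kp$delta_t] == 0))
})

test_that("the package's own quadrature path agrees with the analytic
           integrator", {
  sq <- short_seq()
  kp <- kinetic_params(0.9, 3, 0.3)
  a <- simulate_timecourse(kp, sq)$values
  q <- simulate_timecourse(kp, sq, method = "quadrature",
                           nodes_per_tr = 300L)$values
  expect_lt(max(abs(a - q)) / max(a), 1e-6)
})

test_that("batched simulation equals entry-by-entry simulation", {
  sq <- short_seq()
  tab <- data.frame(delta_t = c(0.25, 1.1, 0.25),
                    sharpness = c(5, 2, 12),
                    time_to_peak = c(0.1, 0.4, 0.05),
                    amplitude = c(1, 2, 0.5))
  batch <- simulate_timecourses(tab, sq)
  for (r in seq_len(nrow(tab))) {
    single <- simulate_timecourse(
      kinetic_params(tab$delta_t[r], tab$sharpness[r],
                     tab$time_to_peak[r], tab$amplitude[r]), sq)$values
    expect_equal(batch[r, ], single, tolerance = 1e-12)
  }
})

test_that("sequence parameters round-trip through YAML", {
  sq <- seq_params(tr = 0.02, labeling_duration = 1.5, n_readouts = 96L,
                   flip_min = 2, flip_max = 9, t1_blood = 1.8,
                   first_excitation_offset = 0.01)
  path <- tempfile(fileext = ".yaml")
  write_seq_config(sq, path)
  back <- read_seq_config(path)
  expect_equal(back, sq)
})
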