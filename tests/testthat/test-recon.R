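test_that("k-space scaling divides by the sort-based 95th percentile", {
  set.seed(21)
  arr <- array(complex(real = rnorm(1000), imaginary = rnorm(1000)),
               dim = c(1, 100, 10))
  sc <- scale_kspace(arr)
  mags <- sort(Mod(as.vector(arr)))
  oracle <- mags[ceiling(0.95 * length(mags))]
  expect_equal(sc$scale_factor, oracle)
  expect_equal(sc$data, arr / oracle, tolerance = 1e-12)
  # constant-magnitude data scales to unit magnitude
  const <- array(3i, dim = c(1, 10, 10))
  expect_equal(Mod(as.vector(scale_kspace(const)$data)), rep(1, 100))
  # undo and rescale reproduces the same factor
  undone <- sc$data * sc$scale_factor
  expect_equal(scale_kspace(undone)$scale_factor, oracle)
  expect_error(scale_kspace(array(0i, dim = c(1, 2, 2))), "all-zero")
})

test_that("coil compression is lossless at full rank and nested below", {
  set.seed(22)
  n_coils <- 6L
  mix <- matrix(complex(real = rnorm(n_coils * 2), imaginary = rnorm(n_coils * 2)),
                n_coils, 2)
  src <- matrix(complex(real = rnorm(2 * 500), imaginary = rnorm(2 * 500)), 2)
  arr <- array(mix %*% src, dim = c(n_coils, 100, 5)) # rank-2 coil data
  full <- compress_coils(arr, n_coils)
  expect_equal(full$energy_retained, 1, tolerance = 1e-12)
  expect_equal(sum(Mod(full$data)^2), sum(Mod(arr)^2), tolerance = 1e-8)
  two <- compress_coils(arr, 2L)
  expect_equal(two$energy_retained, 1, tolerance = 1e-10)
  # rank-1 data needs one virtual coil
  r1 <- array(outer(mix[, 1], as.vector(src[1, ])), dim = c(n_coils, 100, 5))
  expect_equal(compress_coils(r1, 1L)$energy_retained, 1, tolerance = 1e-10)
  ret <- vapply(1:4, function(k) compress_coils(arr, k)$energy_retained,
                numeric(1))
  expect_true(all(diff(ret) >= -1e-12))
  expect_error(compress_coils(arr, 7L), "exceed")
})

test_that("sensitivity estimation returns uniform maps for one coil and
           recovers smooth simulated maps", {
  sc <- small_scene()
  kd <- simulate_kspace(sc$series, sc$sampling, plan = sc$plan)
  uni <- estimate_sensitivities(kd, sc$sampling, bin_size = 4L)
  expect_equal(as.vector(uni), rep(1 + 0i, sc$n^3))
  # smooth synthetic coil profiles over a dense smooth object (the
  # in-vivo use case: a pseudo-structural image with signal everywhere)
  n <- sc$n
  g <- seq(-1, 1, length.out = n)
  gx <- array(rep(g, times = n * n), c(n, n, n))
  gy <- array(rep(rep(g, each = n), times = n), c(n, n, n))
  gz <- array(rep(g, each = n * n), c(n, n, n))
  obj <- exp(-(gx^2 + gy^2 + gz^2) / 0.6)
  static <- image_series(array(rep(obj, sc$seq$n_readouts),
                               c(n, n, n, sc$seq$n_readouts)))
  sens_true <- array(0i, dim = c(n, n, n, 2L))
  sens_true[, , , 1] <- exp(-(gx - 0.4)^2) * exp(1i * 0.4 * gy)
  sens_true[, , , 2] <- exp(-(gx + 0.4)^2) * exp(-1i * 0.3 * gx)
  kd2 <- simulate_kspace(static, sc$sampling, sensitivities = sens_true,
                         plan = sc$plan)
  est <- estimate_sensitivities(kd2, sc$sampling, bin_size = 4L,
                                smooth_width = 1L)
  mask <- attr(est, "mask")
  expect_gt(sum(mask), 0)
  # maps are meaningful where the object has appreciable signal
  strong <- obj > 0.2 * max(obj)
  rss_true <- sqrt(Mod(sens_true[, , , 1])^2 + Mod(sens_true[, , , 2])^2)
  for (cc in 1:2) {
    e <- est[, , , cc][strong]
    # maps are defined up to the voxelwise root-sum-of-squares scale
    t_ <- (sens_true[, , , cc] / rss_true)[strong]
    align <- Mod(sum(Conj(e) * t_)) /
      (sqrt(sum(Mod(e)^2)) * sqrt(sum(Mod(t_)^2)))
    expect_gt(align, 0.99)
  }
  # two identical coils receive equal-magnitude maps
  sens_same <- array(0i, dim = c(n, n, n, 2L))
  sens_same[, , , 1] <- 1
  sens_same[, , , 2] <- 1
  kd3 <- simulate_kspace(sc$series, sc$sampling, sensitivities = sens_same,
                         plan = sc$plan)
  est3 <- estimate_sensitivities(kd3, sc$sampling, bin_size = 4L)
  m3 <- attr(est3, "mask")
  expect_lt(max(abs(Mod(est3[, , , 1][m3]) - Mod(est3[, , , 2][m3]))), 1e-6)
})

test_that("subspace forward and adjoint operators pass the inner-product
           test", {
  sc <- small_scene()
  set.seed(23)
  k <- sc$subspace$k
  n <- sc$n
  x <- array(complex(real = rnorm(n^3 * k), imaginary = rnorm(n^3 * k)),
             dim = c(n, n, n, k))
  y <- matrix(complex(real = rnorm(sc$plan$n_samples),
                      imaginary = rnorm(sc$plan$n_samples)), nrow = 1)
  ax <- forward_subspace(x, sc$subspace, NULL, sc$sampling, sc$plan)
  aty <- adjoint_subspace(y, sc$subspace, NULL, sc$sampling, sc$plan)
  lhs <- sum(Conj(ax) * y)
  rhs <- sum(Conj(x) * aty)
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
  expect_equal(sum(Mod(adjoint_subspace(0 * y, sc$subspace, NULL,
                                        sc$sampling, sc$plan))), 0)
})

test_that("the subspace-domain operator equals expand-then-sample", {
  sc <- small_scene()
  set.seed(24)
  k <- sc$subspace$k
  n <- sc$n
  x <- array(complex(real = rnorm(n^3 * k), imaginary = rnorm(n^3 * k)),
             dim = c(n, n, n, k))
  direct <- forward_subspace(x, sc$subspace, NULL, sc$sampling, sc$plan)
  # naive path: expand to all frames, then frame-wise forward model
  series <- matrix(x, nrow = n^3) %*% t(sc$subspace$basis)
  dim(series) <- c(n, n, n, sc$seq$n_readouts)
  naive <- simulate_kspace(image_series(series), sc$sampling, plan = sc$plan)
  naive <- matrix(naive$data, nrow = 1)
  expect_lt(max(Mod(direct - naive)) / max(Mod(direct)), 1e-8)
})

test_that("the LLR prox is the identity at zero threshold, annihilates
           below-threshold patches, and shrinks singular values exactly", {
  set.seed(25)
  n <- 12L
  k <- 4L
  maps <- array(complex(real = rnorm(n^3 * k), imaginary = rnorm(n^3 * k)),
                dim = c(n, n, n, k))
  expect_identical(llr_prox(maps, 0, 6L), maps, ignore_attr = TRUE)
  big <- llr_prox(maps, 1e6, 6L)
  expect_lt(max(Mod(big)), 1e-9)
  # rank-1 patch with singular value 2, threshold 0.5 -> scaled by 0.75
  r1 <- array(0i, dim = c(n, n, n, k))
  u <- rnorm(6^3); u <- u / sqrt(sum(u^2))
  v <- rnorm(k); v <- v / sqrt(sum(v^2))
  r1[1:6, 1:6, 1:6, ] <- array(2 * outer(u, v), dim = c(6, 6, 6, k))
  shrunk <- llr_prox(r1, 0.5, 6L)
  expect_equal(shrunk, 0.75 * r1, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(attr(shrunk, "nuclear"), 1.5, tolerance = 1e-10)
  # general patches: explicit SVD soft-thresholding oracle
  small <- array(complex(real = rnorm(8^3 * 3)), dim = c(8, 8, 8, 3))
  got <- llr_prox(small, 0.3, 4L)
  for (sx in c(1L, 5L)) {
    m <- matrix(small[sx:(sx + 3), 1:4, 5:8, ], ncol = 3)
    sv <- svd(m)
    ref <- sv$u %*% (pmax(sv$d - 0.3, 0) * Conj(t(sv$v)))
    expect_equal(matrix(got[sx:(sx + 3), 1:4, 5:8, ], ncol = 3), ref,
                 tolerance = 1e-10)
  }
  # cyclic shift moves the partition but keeps the transform exact
  shifted <- llr_prox(small, 0.3, 4L, shift = 2L)
  expect_false(isTRUE(all.equal(shifted, got, check.attributes = FALSE)))
})

test_that("zero data reconstructs to zero coefficients under
           regularization", {
  sc <- small_scene()
  n_samples <- sc$plan$n_samples
  kd0 <- structure(
    list(data = array(0i, dim = c(1L, nrow(sc$sampling$directions),
                                  sc$sampling$samples_per_spoke)),
         noise_sigma = 0, seed = NULL, scale_factor = 1),
    class = "kspace_data")
  cfg <- recon_config(lambda = 1e-3, n_iterations = 5L)
  rec <- reconstruct_subspace(kd0, sc$sampling, sc$subspace, config = cfg,
                              plan = sc$plan)
  expect_equal(sum(Mod(rec$coeffs)), 0)
})

test_that("the regularized objective trace is non-increasing", {
  sc <- small_scene()
  kd <- scale_kspace(simulate_kspace(sc$series, sc$sampling, plan = sc$plan))
  cfg <- recon_config(lambda = 5e-4, n_iterations = 15L)
  rec <- reconstruct_subspace(kd, sc$sampling, sc$subspace, config = cfg,
                              plan = sc$plan)
  expect_true(all(diff(rec$objective) <= 1e-6 * rec$objective[1]))
  cfgb <- recon_config(lambda = 1e-1, n_iterations = 10L, bin_size = 4L)
  recb <- reconstruct_binned(kd, sc$sampling, config = cfgb, plan = sc$plan)
  expect_true(all(diff(recb$objective) <= 1e-6 * recb$objective[1]))
  expect_equal(dim(recb$frames)[4], 4L)
})

test_that("an unregularized reconstruction recovers a representable
           phantom within 2% on the vessel", {
  sc <- small_scene()
  n <- sc$n
  # representable ground truth: Nyquist-ball-limited and basis-projected
  bl <- nyquist_ball_limit(sc$series$data)
  proj <- matrix(bl, nrow = n^3) %*% sc$subspace$basis %*%
    t(sc$subspace$basis)
  truth <- array(proj, dim = dim(sc$series$data))
  kd <- simulate_kspace(image_series(truth), sc$sampling, plan = sc$plan)
  cfg <- recon_config(lambda = 0, n_iterations = 60L)
  rec <- reconstruct_subspace(kd, sc$sampling, sc$subspace, config = cfg,
                              plan = sc$plan)
  vox <- sc$phantom$voxels
  vox_lin <- vox[, 1] + (vox[, 2] - 1) * n + (vox[, 3] - 1) * n^2
  rec_series <- matrix(rec$coeffs, nrow = n^3) %*% t(sc$subspace$basis)
  truth_v <- proj[vox_lin, ]
  nrmse <- sqrt(sum(Mod(rec_series[vox_lin, ] - truth_v)^2) /
                  sum(Mod(truth_v)^2))
  expect_lt(nrmse, 0.02)
  # residual reaches the noiseless floor
  expect_lt(sqrt(rec$objective[cfg$n_iterations] / sum(Mod(kd$data)^2)),
            1e-2)
})

test_that("degenerate binning reconstructs a single static frame", {
  sc <- small_scene()
  kd <- scale_kspace(simulate_kspace(sc$series, sc$sampling, plan = sc$plan))
  cfg <- recon_config(lambda = 1e-1, n_iterations = 8L,
                      bin_size = sc$seq$n_readouts)
  rec <- reconstruct_binned(kd, sc$sampling, config = cfg, plan = sc$plan)
  expect_equal(dim(rec$frames)[4], 1L)
})

test_that("stronger regularization never increases the total nuclear
           norm of the solution", {
  sc <- small_scene()
  kd <- scale_kspace(simulate_kspace(sc$series, sc$sampling, plan = sc$plan))
  nuc <- vapply(c(1e-4, 1e-3, 1e-2), function(lam) {
    cfg <- recon_config(lambda = lam, n_iterations = 12L)
    rec <- reconstruct_subspace(kd, sc$sampling, sc$subspace, config = cfg,
                                plan = sc$plan)
    subangio:::.llr_value(rec$coeffs, 6L)
  }, numeric(1))
  expect_true(all(diff(nuc) <= 1e-8 + 1e-6 * nuc[1]))
})
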