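#' Reconstruction configuration
#'
#' @param lambda Locally-low-rank (LLR) regularization weight, valid under
#'   the 95th-percentile k-space scaling convention (see [scale_kspace()]).
#'   Default 5e-4, the subspace-reconstruction weight; the temporal-binning
#'   baseline conventionally uses 1e-1.
#' @param patch_size LLR patch edge length in voxels.
#' @param n_iterations Accelerated proximal-gradient iterations.
#' @param bin_size Timepoints per frame for the binning reconstruction.
#' @param shift_schedule `"fixed"` (default) keeps one patch partition for
#'   all iterations so the optimized objective is a single function with a
#'   provably monotone trace; `"cycle"` applies a deterministic cyclic
#'   patch shift per iteration to suppress blocking artifacts.
#' @param monotone Use the monotone variant of the accelerated solver.
#' @param power_iters Power-method iterations for the step-size estimate.
#' @param nufft_width Kaiser-Bessel kernel width for the gridding
#'   non-uniform FFT inside the reconstruction (default 6; 4 is faster
#'   with accuracy still far below the regularization scale).
#' @param solver `"auto"` (default) uses the accelerated proximal-gradient
#'   solver when `lambda > 0` and density-weighted conjugate gradients on
#'   the normal equations when `lambda = 0`; `"fista"` or `"cg"` force one
#'   (`"cg"` requires `lambda = 0`).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(lambda = 5e-4, patch_size = 6L, n_iterations = 100L,
                         bin_size = 12L, shift_schedule = c("fixed", "cycle"),
                         monotone = TRUE, power_iters = 8L,
                         solver = c("auto", "fista", "cg"),
                         nufft_width = 6L) {
  stopifnot(lambda >= 0, patch_size >= 2, n_iterations >= 1, bin_size >= 1,
            nufft_width >= 2)
  solver <- match.arg(solver)
  if (solver == "cg" && lambda > 0)
    stop("the conjugate-gradient solver applies only to lambda = 0")
  structure(
    list(lambda = lambda, patch_size = as.integer(patch_size),
         n_iterations = as.integer(n_iterations),
         bin_size = as.integer(bin_size),
         shift_schedule = match.arg(shift_schedule),
         monotone = isTRUE(monotone),
         power_iters = as.integer(power_iters),
         solver = solver,
         nufft_width = as.integer(nufft_width)),
    class = "recon_config"
  )
}

.resolve_solver <- function(config) {
  if (config$solver != "auto") return(config$solver)
  if (config$lambda == 0) "cg" else "fista"
}

#' Scale k-space data by its 95th-percentile magnitude
#'
#' Divides all complex samples by the 95th percentile (sort-based, inverse
#' empirical CDF) of the pooled sample magnitudes, recording the factor so
#' the scaling can be undone. Normalizing data this way makes one LLR
#' regularization weight transferable between simulated and acquired data.
#'
#' @param data A `kspace_data` object or complex array.
#' @param probs Percentile used for scaling (default 0.95).
#' @return A `kspace_data` object with unit-scale data and `scale_factor`
#'   set to the divisor.
#' @export
scale_kspace <- function(data, probs = 0.95) {
  arr <- if (inherits(data, "kspace_data")) data$data else data
  mags <- Mod(as.vector(arr))
  if (all(mags == 0)) stop("cannot scale all-zero k-space data")
  fac <- as.numeric(stats::quantile(mags, probs, type = 1, names = FALSE))
  out <- if (inherits(data, "kspace_data")) data else
    structure(list(data = arr, noise_sigma = 0, seed = NULL,
                   scale_factor = 1), class = "kspace_data")
  out$data <- arr / fac
  out$scale_factor <- out$scale_factor * fac
  out
}

#' Compress coil channels by principal component analysis
#'
#' Finds the linear channel combination maximizing retained signal energy
#' (eigenvectors of the sample covariance across channels, pooled over all
#' k-space samples) and keeps the leading `n_virtual` virtual coils.
#'
#' @param data A `kspace_data` object or complex array with the coil
#'   dimension first.
#' @param n_virtual Number of virtual coils to retain.
#' @return List with `data` (compressed, same class as input), `mixing`
#'   (coils x n_virtual unitary matrix) and `energy_retained` (fraction).
#' @export
compress_coils <- function(data, n_virtual = 8L) {
  is_kd <- inherits(data, "kspace_data")
  arr <- if (is_kd) data$data else data
  d <- dim(arr)
  n_coils <- d[1]
  if (n_virtual > n_coils) stop("`n_virtual` must not exceed the coil count")
  x <- matrix(arr, nrow = n_coils)
  cov <- x %*% Conj(t(x))
  eg <- eigen(cov, symmetric = TRUE)
  v <- eg$vectors[, seq_len(n_virtual), drop = FALSE]
  comp <- Conj(t(v)) %*% x
  dim(comp) <- c(n_virtual, d[-1])
  out <- if (is_kd) { data$data <- comp; data } else comp
  list(
    data = out,
    mixing = v,
    energy_retained = sum(eg$values[seq_len(n_virtual)]) / sum(eg$values)
  )
}

#' Estimate coil sensitivity maps from late-frame k-space data
#'
#' Grids density-compensated data from the last two temporally binned
#' frames (when the vasculature is fully filled) into low-resolution
#' coilwise images, then applies a blockwise adaptive-combination (Walsh)
#' estimate: the dominant eigenvector of the spatially smoothed coil
#' covariance at every voxel. Maps are normalized to unit root-sum-of-
#' squares (eigenvectors are unit norm) with the phase referenced to the
#' strongest coil. For in vivo use the input should be the mean of tag and
#' control data; the synthetic path passes difference data directly.
#'
#' @param data A `kspace_data` object (coils x spokes x samples).
#' @param sampling The matching [build_sampling()] object.
#' @param bin_size Timepoints per bin used to define "the last two frames".
#' @param smooth_width Box-smoothing width (voxels) for the coil
#'   covariance.
#' @return Complex array `n x n x n x n_coils` with unit root-sum-of-squares
#'   at every voxel; the support mask (gridded intensity above 5% of
#'   maximum) is attached as attribute `"mask"`.
#' @export
estimate_sensitivities <- function(data, sampling, bin_size = 12L,
                                   smooth_width = NULL) {
  stopifnot(inherits(data, "kspace_data"),
            inherits(sampling, "kspace_sampling"))
  n <- sampling$matrix_size
  n_coils <- dim(data$data)[1]
  if (is.null(smooth_width)) smooth_width <- max(3L, n %/% 8L)
  if (n_coils == 1L) {
    out <- array(1 + 0i, dim = c(n, n, n, 1L))
    attr(out, "mask") <- array(TRUE, dim = c(n, n, n))
    return(out)
  }
  bins <- bin_frames(sampling$n_timepoints, bin_size)
  last2 <- bins[(nrow(bins) - 1):nrow(bins), ]
  tps <- seq(last2$first[1], last2$last[2])
  spokes <- as.vector(sampling$assignment[tps, ])
  n_spokes <- nrow(sampling$directions)
  sps <- sampling$samples_per_spoke
  subset <- as.vector(outer(spokes, (seq_len(sps) - 1L) * n_spokes, "+"))
  plan <- nufft_plan(n, sampling$coords)
  # density compensation plus a radial Hamming window: a smooth low-pass
  # that suppresses ringing in the coilwise images
  r <- sqrt(rowSums(matrix(sampling$coords, ncol = 3)^2)) / 0.5
  w <- (radial_dcf(sampling$coords) *
          (0.54 + 0.46 * cos(pi * pmin(r, 1))))[subset]
  imgs <- array(0i, dim = c(n, n, n, n_coils))
  for (cc in seq_len(n_coils)) {
    y <- matrix(data$data[cc, , ], nrow = n_spokes)[cbind(
      rep(spokes, times = sps), rep(seq_len(sps), each = length(spokes)))]
    imgs[, , , cc] <- nufft_adjoint(plan, w * y, subset = subset)
  }
  # voxelwise dominant eigenvector of the smoothed coil covariance
  sens <- array(0i, dim = c(n, n, n, n_coils))
  cov <- array(0i, dim = c(n, n, n, n_coils, n_coils))
  for (a in seq_len(n_coils)) {
    for (b in seq_len(n_coils)) {
      cov[, , , a, b] <- .box_smooth3(imgs[, , , a] * Conj(imgs[, , , b]),
                                      smooth_width)
    }
  }
  covm <- matrix(cov, nrow = n^3)
  # phase referenced to one fixed coil (the strongest overall) so the maps
  # vary smoothly in space
  ref_coil <- which.max(vapply(seq_len(n_coils), function(cc) {
    sum(Mod(imgs[, , , cc])^2)
  }, numeric(1)))
  sm <- matrix(0i, n^3, n_coils)
  for (v in seq_len(n^3)) {
    m <- matrix(covm[v, ], n_coils, n_coils)
    eg <- eigen(m, symmetric = TRUE)
    vec <- eg$vectors[, 1]
    ph <- vec[ref_coil]
    if (Mod(ph) > 0) vec <- vec * Conj(ph) / Mod(ph)
    sm[v, ] <- vec
  }
  sens <- array(sm, dim = c(n, n, n, n_coils))
  rss <- sqrt(apply(Mod(imgs)^2, 1:3, sum))
  attr(sens, "mask") <- rss > 0.05 * max(rss)
  sens
}

# Separable circular box smoothing of a 3D (complex) array.
.box_smooth3 <- function(x, width) {
  if (width <= 1) return(x)
  n <- dim(x)[1]
  kern <- rep(1 / width, width)
  sm1 <- function(v) {
    # circular convolution via FFT along the first dimension
    m <- matrix(v, nrow = n)
    kf <- stats::fft(c(kern, rep(0, n - width)))
    shift <- exp(2i * pi * (0:(n - 1)) * ((width - 1) / 2) / n)
    apply(m, 2, function(col) stats::fft(stats::fft(col) * kf * shift,
                                         inverse = TRUE) / n)
  }
  d <- dim(x)
  out <- array(sm1(x), dim = d)
  out <- aperm(array(sm1(aperm(out, c(2, 1, 3))), dim = d[c(2, 1, 3)]),
               c(2, 1, 3))
  aperm(array(sm1(aperm(out, c(3, 1, 2))), dim = d[c(3, 1, 2)]),
        c(2, 3, 1))
}

# Per-sample temporal weights of each subspace component: sample ordering
# is spoke-major (spoke index varies fastest), matching flattened coords.
.sample_weights <- function(sampling, basis) {
  tp <- rep(sampling$timepoint_of_spoke, times = sampling$samples_per_spoke)
  basis[tp, , drop = FALSE]
}

#' Subspace-domain forward and adjoint acquisition operators
#'
#' `forward_subspace()` maps subspace coefficient maps to predicted
#' k-space: for each component the coil-weighted map is transformed once by
#' the non-uniform FFT at all sample coordinates and then modulated by that
#' component's temporal weight at each sample's timepoint (the operator
#' order `P Phi F C`), so no full time series is ever materialized.
#' `adjoint_subspace()` is the exact adjoint.
#'
#' @param coeffs Complex array `n x n x n x K` of coefficient maps.
#' @param basis Temporal basis (`temporal_subspace` or timepoints x K
#'   matrix).
#' @param sens Coil sensitivities `n x n x n x n_coils` (or `NULL` for a
#'   single uniform coil).
#' @param sampling A [build_sampling()] object.
#' @param plan Optional precomputed [nufft_plan()] over all coordinates.
#' @return `forward_subspace`: complex matrix `n_coils x n_samples`;
#'   `adjoint_subspace`: complex array `n x n x n x K`.
#' @export
forward_subspace <- function(coeffs, basis, sens, sampling, plan = NULL) {
  phi <- .basis_matrix(basis)
  n <- sampling$matrix_size
  k <- ncol(phi)
  stopifnot(all(dim(coeffs) == c(n, n, n, k)))
  if (is.null(sens)) sens <- array(1 + 0i, dim = c(n, n, n, 1L))
  n_coils <- dim(sens)[4]
  if (is.null(plan)) plan <- nufft_plan(n, sampling$coords)
  w <- .sample_weights(sampling, phi)
  pred <- matrix(0i, n_coils, plan$n_samples)
  for (kk in seq_len(k)) {
    for (cc in seq_len(n_coils)) {
      f <- nufft_forward(plan, sens[, , , cc] * coeffs[, , , kk])
      pred[cc, ] <- pred[cc, ] + w[, kk] * f
    }
  }
  pred
}

#' @rdname forward_subspace
#' @param kspace Complex matrix `n_coils x n_samples` (or vector for a
#'   single coil).
#' @export
adjoint_subspace <- function(kspace, basis, sens, sampling, plan = NULL) {
  phi <- .basis_matrix(basis)
  n <- sampling$matrix_size
  k <- ncol(phi)
  if (is.null(dim(kspace))) kspace <- matrix(kspace, nrow = 1)
  if (is.null(sens)) sens <- array(1 + 0i, dim = c(n, n, n, 1L))
  n_coils <- dim(sens)[4]
  stopifnot(nrow(kspace) == n_coils)
  if (is.null(plan)) plan <- nufft_plan(n, sampling$coords)
  w <- .sample_weights(sampling, phi)
  out <- array(0i, dim = c(n, n, n, k))
  for (kk in seq_len(k)) {
    acc <- array(0i, dim = c(n, n, n))
    for (cc in seq_len(n_coils)) {
      g <- nufft_adjoint(plan, w[, kk] * kspace[cc, ])
      acc <- acc + Conj(sens[, , , cc]) * g
    }
    out[, , , kk] <- acc
  }
  out
}

#' Proximal operator of the locally-low-rank penalty
#'
#' Partitions the volume into non-overlapping cubes of `patch_size`
#' (optionally cyclically shifted), forms the (patch voxels x K) matrix of
#' each patch across the last array dimension, soft-thresholds its
#' singular values by `threshold`, and reassembles. This is the exact
#' proximal operator of `threshold * sum of patch nuclear norms` under the
#' given partition. The nuclear norm of the result is attached as
#' attribute `"nuclear"`.
#'
#' @param maps Complex array `n x n x n x K` (coefficient maps or binned
#'   frames).
#' @param threshold Singular-value soft threshold (>= 0).
#' @param patch_size Patch edge length in voxels.
#' @param shift Integer 3-vector (or scalar) cyclic shift of the partition.
#' @return Array of the same shape.
#' @export
llr_prox <- function(maps, threshold, patch_size = 6L, shift = 0L) {
  stopifnot(threshold >= 0, length(dim(maps)) == 4L)
  if (threshold == 0) {
    attr(maps, "nuclear") <- NA_real_
    return(maps)
  }
  n <- dim(maps)[1]
  k <- dim(maps)[4]
  shift <- rep_len(as.integer(shift), 3L)
  if (any(shift %% n != 0)) {
    idx <- lapply(1:3, function(d) ((seq_len(n) - 1 + shift[d]) %% n) + 1)
    maps <- maps[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  }
  starts <- seq(1L, n, by = patch_size)
  nuclear <- 0
  for (sx in starts) {
    ix <- sx:min(sx + patch_size - 1L, n)
    for (sy in starts) {
      iy <- sy:min(sy + patch_size - 1L, n)
      for (sz in starts) {
        iz <- sz:min(sz + patch_size - 1L, n)
        patch <- maps[ix, iy, iz, , drop = FALSE]
        m <- matrix(patch, ncol = k)
        sv <- svd(m)
        d2 <- pmax(sv$d - threshold, 0)
        nuclear <- nuclear + sum(d2)
        m2 <- sv$u %*% (d2 * Conj(t(sv$v)))
        maps[ix, iy, iz, ] <- array(m2, dim = dim(patch))
      }
    }
  }
  if (any(shift %% n != 0)) {
    idx <- lapply(1:3, function(d) ((seq_len(n) - 1 - shift[d]) %% n) + 1)
    maps <- maps[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  }
  attr(maps, "nuclear") <- nuclear
  maps
}

# Nuclear-norm value of the LLR penalty (without proximal step).
.llr_value <- function(maps, patch_size, shift = 0L) {
  n <- dim(maps)[1]
  k <- dim(maps)[4]
  shift <- rep_len(as.integer(shift), 3L)
  if (any(shift %% n != 0)) {
    idx <- lapply(1:3, function(d) ((seq_len(n) - 1 + shift[d]) %% n) + 1)
    maps <- maps[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  }
  starts <- seq(1L, n, by = patch_size)
  total <- 0
  for (sx in starts) for (sy in starts) for (sz in starts) {
    ix <- sx:min(sx + patch_size - 1L, n)
    iy <- sy:min(sy + patch_size - 1L, n)
    iz <- sz:min(sz + patch_size - 1L, n)
    m <- matrix(maps[ix, iy, iz, , drop = FALSE], ncol = k)
    total <- total + sum(svd(m, nu = 0, nv = 0)$d)
  }
  total
}

# Monotone accelerated proximal gradient (MFISTA) for
#   min_x ||A x - y||^2 + lambda * g(x),
# with prox_g supplied. One forward and one adjoint application per
# iteration: A z at the momentum point is formed from cached forwards by
# linearity. Returns x, the objective trace and the step size.
.fista <- function(A, At, y, prox, g_value, x0, lambda, n_iter,
                   step, monotone = TRUE) {
  x_prev <- x0
  ax_prev <- A(x0)
  g_prev <- if (lambda > 0) g_value(x0) else 0
  f_prev <- sum(Mod(ax_prev - y)^2)
  obj_prev <- f_prev + lambda * g_prev
  x_cur <- x_prev; ax_cur <- ax_prev; obj_cur <- obj_prev
  z <- x_prev; az <- ax_prev
  t_cur <- 1
  trace <- numeric(n_iter)
  bad_steps <- 0L
  for (it in seq_len(n_iter)) {
    grad <- At(az - y)
    cand <- z - step * grad
    if (lambda > 0) {
      cand <- prox(cand, step * lambda, it)
      g_cand <- attr(cand, "nuclear")
      attr(cand, "nuclear") <- NULL
    } else {
      g_cand <- 0
    }
    a_cand <- A(cand)
    obj_cand <- sum(Mod(a_cand - y)^2) + lambda * g_cand
    t_new <- (1 + sqrt(1 + 4 * t_cur^2)) / 2
    if (monotone && obj_cand > obj_cur) {
      x_new <- x_cur; ax_new <- ax_cur; obj_new <- obj_cur
    } else {
      x_new <- cand; ax_new <- a_cand; obj_new <- obj_cand
    }
    z <- x_new + (t_cur / t_new) * (cand - x_new) +
      ((t_cur - 1) / t_new) * (x_new - x_cur)
    az <- ax_new + (t_cur / t_new) * (a_cand - ax_new) +
      ((t_cur - 1) / t_new) * (ax_new - ax_cur)
    if (obj_new > obj_cur * (1 + 1e-6)) bad_steps <- bad_steps + 1L
    else bad_steps <- 0L
    if (bad_steps > 5L) {
      stop("reconstruction diverged: objective increased for >5 iterations; ",
           "trace: ", paste(signif(trace[seq_len(it - 1)], 6), collapse = ", "))
    }
    x_cur <- x_new; ax_cur <- ax_new; obj_cur <- obj_new
    t_cur <- t_new
    trace[it] <- obj_new
  }
  list(x = x_cur, objective = trace, step = step)
}

# Conjugate gradients on the (optionally density-weighted) normal
# equations A^H W A x = A^H W y. Used for unregularized (lambda = 0)
# reconstructions: with exactly model-consistent data any positive
# weighting preserves the solution, and radial density compensation
# dramatically improves conditioning (CG-SENSE-style). A(p) is cached so
# the weighted data objective comes at no extra operator cost; in exact
# arithmetic it is non-increasing over CG iterations.
.cg_normal <- function(A, At, y, x0, n_iter, weights = NULL) {
  wmul <- if (is.null(weights)) identity else
    function(r) sweep(r, 2, weights, "*")
  x <- x0
  ax <- A(x)
  r <- At(wmul(y - ax))
  p <- r
  rs <- sum(Mod(r)^2)
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    if (rs == 0) { trace[it:n_iter] <- trace[max(it - 1, 1)]; break }
    ap_data <- A(p)
    ap <- At(wmul(ap_data))
    alpha <- rs / Re(sum(Conj(p) * ap))
    x <- x + alpha * p
    ax <- ax + alpha * ap_data
    r <- r - alpha * ap
    rs_new <- sum(Mod(r)^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    resid <- ax - y
    trace[it] <- if (is.null(weights)) sum(Mod(resid)^2) else
      sum(sweep(Mod(resid)^2, 2, weights, "*"))
  }
  list(x = x, objective = trace, step = NA_real_)
}

# Largest-eigenvalue (squared operator norm) estimate by power iteration.
.power_normsq <- function(A, At, x_init, iters = 8L) {
  v <- x_init
  nv <- sqrt(sum(Mod(v)^2))
  if (nv == 0) return(1)
  v <- v / nv
  lam <- 1
  for (i in seq_len(iters)) {
    w <- At(A(v))
    lam <- sqrt(sum(Mod(w)^2))
    if (lam == 0) return(1)
    v <- w / lam
  }
  lam
}

#' Subspace-constrained image reconstruction
#'
#' Solves
#' `min_alpha ||P F C Phi alpha - y||^2 + lambda * sum_i ||W_i(alpha)||_*`
#' by monotone accelerated proximal gradient descent, entirely in the
#' subspace domain: the temporal combination uses precomputed per-sample
#' basis weights, so each iteration costs one forward and one adjoint
#' non-uniform FFT per component and coil. The step size comes from a
#' power-iteration estimate of the operator norm. The initial estimate is
#' the adjoint of density-compensated data scaled by a least-squares fit.
#'
#' @param data A `kspace_data` object (scale it first with
#'   [scale_kspace()] when using the default `lambda`).
#' @param sampling The matching [build_sampling()] object.
#' @param basis Temporal basis (`temporal_subspace` or matrix).
#' @param sens Coil sensitivities (`NULL` = single uniform coil).
#' @param config A [recon_config()].
#' @param plan Optional precomputed [nufft_plan()] over all coordinates.
#' @return An object of class `recon_result`: list with `coeffs`
#'   (`n x n x n x K` complex), `objective` (trace), `config`, `basis`,
#'   `time`, `mode = "subspace"`.
#' @export
reconstruct_subspace <- function(data, sampling, basis, sens = NULL,
                                 config = recon_config(), plan = NULL) {
  stopifnot(inherits(data, "kspace_data"),
            inherits(sampling, "kspace_sampling"),
            inherits(config, "recon_config"))
  phi <- .basis_matrix(basis)
  n <- sampling$matrix_size
  k <- ncol(phi)
  if (is.null(plan))
    plan <- nufft_plan(n, sampling$coords, width = config$nufft_width)
  n_coils <- dim(data$data)[1]
  y <- matrix(data$data, nrow = n_coils) # coils x (spokes*samples)
  A <- function(x) forward_subspace(x, phi, sens, sampling, plan)
  At <- function(r) adjoint_subspace(r, phi, sens, sampling, plan)
  # density-compensated adjoint, least-squares scaled, as initialization
  dcf <- radial_dcf(sampling$coords)
  x0 <- adjoint_subspace(sweep(y, 2, dcf, "*"), phi, sens, sampling, plan)
  ax0 <- A(x0)
  e0 <- sum(Mod(ax0)^2)
  x0 <- if (e0 > 0) x0 * (sum(Conj(ax0) * y) / e0) else 0 * x0
  if (.resolve_solver(config) == "cg") {
    res <- .cg_normal(A, At, y, x0, config$n_iterations, weights = dcf)
  } else {
    normsq <- .power_normsq(A, At, x0, config$power_iters)
    step <- 1 / (1.05 * normsq)
    shifts <- .shift_schedule(config, n)
    prox <- function(x, thr, it) {
      llr_prox(x, thr / 2, config$patch_size,
               shifts[[(it - 1) %% length(shifts) + 1]])
    }
    g_val <- function(x) .llr_value(x, config$patch_size, shifts[[1]])
    res <- .fista(A, At, y, prox, g_val, x0, config$lambda,
                  config$n_iterations, step, config$monotone)
  }
  structure(
    list(coeffs = res$x, objective = res$objective, config = config,
         basis = phi, mode = "subspace", step = res$step),
    class = "recon_result"
  )
}

.shift_schedule <- function(config, n) {
  if (config$shift_schedule == "fixed") return(list(c(0L, 0L, 0L)))
  p <- config$patch_size
  lapply(0:(p - 1), function(s) rep(s %% n, 3L))
}

#' Temporal-binning image reconstruction
#'
#' The baseline method: groups readouts of `bin_size` adjacent timepoints
#' into each frame and solves
#' `min_x ||P F C x - y||^2 + lambda * sum_i ||W_i(x)||_*`
#' with the LLR penalty across the binned-frame dimension, using the same
#' monotone accelerated solver as [reconstruct_subspace()].
#'
#' @inheritParams reconstruct_subspace
#' @param config A [recon_config()]; `config$bin_size` frames per bin and
#'   `config$lambda` (conventionally 1e-1 for this method) are used.
#' @return A `recon_result` with `frames` (`n x n x n x n_bins` complex),
#'   `bins` (the [bin_frames()] table) and `mode = "binned"`.
#' @export
reconstruct_binned <- function(data, sampling, sens = NULL,
                               config = recon_config(lambda = 1e-1),
                               plan = NULL) {
  stopifnot(inherits(data, "kspace_data"),
            inherits(sampling, "kspace_sampling"),
            inherits(config, "recon_config"))
  n <- sampling$matrix_size
  bins <- bin_frames(sampling$n_timepoints, config$bin_size)
  n_bins <- nrow(bins)
  if (is.null(plan))
    plan <- nufft_plan(n, sampling$coords, width = config$nufft_width)
  n_coils <- dim(data$data)[1]
  n_spokes <- nrow(sampling$directions)
  sps <- sampling$samples_per_spoke
  if (is.null(sens)) sens <- array(1 + 0i, dim = c(n, n, n, 1L))
  # per-bin sample subsets (spoke-major flattened ordering)
  subsets <- lapply(seq_len(n_bins), function(b) {
    spokes <- as.vector(sampling$assignment[bins$first[b]:bins$last[b], ])
    as.vector(outer(spokes, (seq_len(sps) - 1L) * n_spokes, "+"))
  })
  y <- matrix(data$data, nrow = n_coils)
  A <- function(x) {
    pred <- matrix(0i, n_coils, ncol(y))
    for (b in seq_len(n_bins)) {
      for (cc in seq_len(n_coils)) {
        pred[cc, subsets[[b]]] <- nufft_forward(
          plan, sens[, , , cc] * x[, , , b], subset = subsets[[b]])
      }
    }
    pred
  }
  At <- function(r) {
    out <- array(0i, dim = c(n, n, n, n_bins))
    for (b in seq_len(n_bins)) {
      acc <- array(0i, dim = c(n, n, n))
      for (cc in seq_len(n_coils)) {
        acc <- acc + Conj(sens[, , , cc]) *
          nufft_adjoint(plan, r[cc, subsets[[b]]], subset = subsets[[b]])
      }
      out[, , , b] <- acc
    }
    out
  }
  dcf <- radial_dcf(sampling$coords)
  x0 <- At(sweep(y, 2, dcf, "*"))
  ax0 <- A(x0)
  e0 <- sum(Mod(ax0)^2)
  x0 <- if (e0 > 0) x0 * (sum(Conj(ax0) * y) / e0) else 0 * x0
  if (.resolve_solver(config) == "cg") {
    res <- .cg_normal(A, At, y, x0, config$n_iterations, weights = dcf)
  } else {
    normsq <- .power_normsq(A, At, x0, config$power_iters)
    step <- 1 / (1.05 * normsq)
    shifts <- .shift_schedule(config, n)
    prox <- function(x, thr, it) {
      llr_prox(x, thr / 2, config$patch_size,
               shifts[[(it - 1) %% length(shifts) + 1]])
    }
    g_val <- function(x) .llr_value(x, config$patch_size, shifts[[1]])
    res <- .fista(A, At, y, prox, g_val, x0, config$lambda,
                  config$n_iterations, step, config$monotone)
  }
  structure(
    list(frames = res$x, objective = res$objective, config = config,
         bins = bins, mode = "binned", step = res$step),
    class = "recon_result"
  )
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("recon_result (%s): %d iterations, final objective %.6g\n",
              x$mode, length(x$objective), utils::tail(x$objective, 1)))
  invisible(x)
}

#' Expand a subspace reconstruction to a full image series
#'
#' @param result A `recon_result` from [reconstruct_subspace()].
#' @param time Optional time axis for the series.
#' @return An [image_series()] with one frame per timepoint.
#' @export
expand_recon <- function(result, time = NULL) {
  stopifnot(inherits(result, "recon_result"), result$mode == "subspace")
  d <- dim(result$coeffs)
  n_vox <- prod(d[1:3])
  k <- d[4]
  series <- matrix(result$coeffs, nrow = n_vox) %*% t(result$basis)
  dim(series) <- c(d[1:3], nrow(result$basis))
  image_series(series, time = time)
}
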