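#' Single-vessel numerical phantom
#'
#' A one-voxel-wide straight vessel crossing the center of a cubic volume
#' along one grid axis. Kinetic parameters vary linearly along the vessel
#' from the entry side (fast arrival, little dispersion) to the exit side
#' (late arrival, strong dispersion); the amplitude is constant on the
#' vessel and zero elsewhere. Defaults emulate increasing transit time and
#' dispersion along an artery: transit time 0.25-1.8 s, time-to-peak
#' 0.1-0.5 s, sharpness 1-10 1/s, amplitude 1.
#'
#' @param matrix_size Volume size in voxels per dimension (>= 8).
#' @param delta_t_range,time_to_peak_range,sharpness_range Linear ramp
#'   endpoints (entry, exit) for each kinetic parameter.
#' @param amplitude Amplitude on the vessel.
#' @param axis Grid axis (1, 2 or 3) the vessel runs along.
#' @return An object of class `vessel_phantom`: list with `matrix_size`,
#'   `axis`, `voxels` (n x 3 integer matrix of 1-based vessel voxel
#'   indices) and `params` (data frame of per-voxel kinetic parameters).
#' @export
vessel_phantom <- function(matrix_size = 64L,
                           delta_t_range = c(0.25, 1.8),
                           time_to_peak_range = c(0.1, 0.5),
                           sharpness_range = c(1, 10),
                           amplitude = 1,
                           axis = 1L) {
  n <- as.integer(matrix_size)
  stopifnot(n >= 8, axis %in% 1:3)
  ramp <- function(r) seq(r[1], r[2], length.out = n)
  cen <- n %/% 2L + 1L
  voxels <- matrix(cen, nrow = n, ncol = 3L)
  voxels[, axis] <- seq_len(n)
  structure(
    list(
      matrix_size = n,
      axis = as.integer(axis),
      voxels = voxels,
      params = data.frame(
        delta_t = ramp(delta_t_range),
        sharpness = ramp(sharpness_range),
        time_to_peak = ramp(time_to_peak_range),
        amplitude = amplitude
      )
    ),
    class = "vessel_phantom"
  )
}

#' @export
print.vessel_phantom <- function(x, ...) {
  cat(sprintf(
    "vessel_phantom: %d^3 volume, vessel along axis %d (%d voxels)\n",
    x$matrix_size, x$axis, nrow(x$voxels)))
  invisible(x)
}

#' Ground-truth timecourses of the vessel voxels
#'
#' @param phantom A [vessel_phantom()].
#' @param seq A [seq_params()] object.
#' @return Matrix `n_vessel_voxels` x `n_readouts`.
#' @export
vessel_timecourses <- function(phantom, seq) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  simulate_timecourses(phantom$params, seq)
}

#' Simulate the 4D image series of a phantom
#'
#' Evaluates the kinetic model voxelwise: vessel voxels carry their
#' simulated timecourse, all other voxels are zero. The series is stored
#' complex (imaginary part zero) because reconstruction operates on
#' complex images.
#'
#' @inheritParams vessel_timecourses
#' @return An object of class `image_series`: list with `data` (complex
#'   array `n x n x n x n_readouts`), `time` (seconds after labeling
#'   onset), `voxel_mm`.
#' @export
phantom_series <- function(phantom, seq) {
  stopifnot(inherits(phantom, "vessel_phantom"), inherits(seq, "seq_params"))
  n <- phantom$matrix_size
  tc <- vessel_timecourses(phantom, seq)
  dat <- array(0i, dim = c(n, n, n, seq$n_readouts))
  vox_lin <- phantom$voxels[, 1] +
    (phantom$voxels[, 2] - 1L) * n +
    (phantom$voxels[, 3] - 1L) * n^2
  frame_stride <- as.double(n)^3
  for (i in seq_len(seq$n_readouts)) {
    dat[vox_lin + (i - 1) * frame_stride] <- tc[, i]
  }
  image_series(dat, time = excitation_times(seq))
}

#' Construct an image series container
#'
#' @param data Complex 4D array (`x, y, z, time`).
#' @param time Time axis in seconds (length = 4th dimension).
#' @param voxel_mm Isotropic voxel size in millimeters.
#' @return An object of class `image_series`.
#' @export
image_series <- function(data, time = NULL, voxel_mm = 1.13) {
  stopifnot(length(dim(data)) == 4L)
  if (!is.complex(data)) data <- data + 0i
  if (is.null(time)) time <- seq_len(dim(data)[4])
  stopifnot(length(time) == dim(data)[4])
  structure(list(data = data, time = time, voxel_mm = voxel_mm),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_series: %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Simulate non-Cartesian k-space acquisition of an image series
#'
#' For each timepoint, the frame (weighted by each coil sensitivity) is
#' transformed by the forward non-uniform FFT and evaluated at the
#' coordinates of the spokes assigned to that timepoint (all repeats). The
#' phantom series plays the role of the control-label difference signal, so
#' no tag/control pairing is simulated. Optional i.i.d. circular complex
#' Gaussian noise (per-sample standard deviation `noise_sigma`, split
#' equally between real and imaginary parts) is generated from `seed`.
#'
#' @param series An [image_series()] (or complex 4D array).
#' @param sampling A [build_sampling()] object with `n_timepoints` equal to
#'   the number of frames and `matrix_size` equal to the image size.
#' @param sensitivities Optional complex array `n x n x n x n_coils`;
#'   `NULL` means a single uniform coil.
#' @param noise_sigma Complex noise standard deviation (0 = noiseless).
#' @param seed Integer seed recorded and used for the noise draw.
#' @param plan Optional precomputed [nufft_plan()] over all sampling
#'   coordinates (built internally when omitted).
#' @return An object of class `kspace_data`: list with `data` (complex
#'   array `n_coils x n_spokes x samples_per_spoke`), `noise_sigma`,
#'   `seed`, `scale_factor` (1 until [scale_kspace()] is applied).
#' @export
simulate_kspace <- function(series, sampling, sensitivities = NULL,
                            noise_sigma = 0, seed = NULL, plan = NULL) {
  if (inherits(series, "image_series")) series <- series$data
  stopifnot(length(dim(series)) == 4L,
            inherits(sampling, "kspace_sampling"))
  n <- sampling$matrix_size
  if (!all(dim(series)[1:3] == n))
    stop("image grid does not match the sampling matrix size")
  if (dim(series)[4] != sampling$n_timepoints)
    stop("number of frames does not match the sampling timepoints")
  if (is.null(sensitivities)) {
    sensitivities <- array(1 + 0i, dim = c(n, n, n, 1L))
  }
  stopifnot(all(dim(sensitivities)[1:3] == n))
  n_coils <- dim(sensitivities)[4]
  if (is.null(plan)) plan <- nufft_plan(n, sampling$coords)
  n_spokes <- nrow(sampling$directions)
  sps <- sampling$samples_per_spoke
  dat <- array(0i, dim = c(n_coils, n_spokes, sps))
  for (i in seq_len(sampling$n_timepoints)) {
    spokes_i <- sampling$assignment[i, ]
    subset <- as.vector(outer(spokes_i, (seq_len(sps) - 1L) * n_spokes, "+"))
    frame <- series[, , , i]
    for (cc in seq_len(n_coils)) {
      vals <- nufft_forward(plan, sensitivities[, , , cc] * frame,
                            subset = subset)
      dat[cc, spokes_i, ] <- vals
    }
  }
  if (noise_sigma > 0) {
    if (is.null(seed)) seed <- 1L
    noise <- .with_seed(seed, {
      m <- length(dat)
      complex(real = stats::rnorm(m, sd = noise_sigma / sqrt(2)),
              imaginary = stats::rnorm(m, sd = noise_sigma / sqrt(2)))
    })
    dat <- dat + array(noise, dim = dim(dat))
  }
  structure(
    list(data = dat, noise_sigma = noise_sigma, seed = seed,
         scale_factor = 1),
    class = "kspace_data"
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "kspace_data: %d coil(s), %d spokes x %d samples (noise sd %.3g)\n",
    d[1], d[2], d[3], x$noise_sigma))
  invisible(x)
}
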