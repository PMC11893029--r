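#' The two 3D golden means
#'
#' The pair of irrational increments generalizing the golden angle to 3D
#' radial ("kooshball") sampling: with `psi` the real root of
#' `x^3 - x^2 - 1 = 0`, `phi1 = 1/psi` (azimuthal increment, ~0.6823) and
#' `phi2 = 1/psi^2` (polar increment, ~0.4656). Successive spokes advance
#' the azimuthal angle by `2*pi*phi1` and the cosine of the polar angle by
#' `phi2` (both modulo 1 turn), giving near-uniform incremental coverage of
#' the sphere.
#'
#' @return Named numeric vector `c(phi1 = ..., phi2 = ...)`.
#' @export
golden_means <- function() {
  psi <- polyroot(c(-1, 0, -1, 1)) # roots of x^3 - x^2 - 1
  psi <- Re(psi[which.min(abs(Im(psi)))])
  # one Newton step polishes the root to full double precision
  psi <- psi - (psi^3 - psi^2 - 1) / (3 * psi^2 - 2 * psi)
  c(phi1 = 1 / psi, phi2 = 1 / psi^2)
}

#' Direction of the m-th golden-ratio radial spoke
#'
#' Azimuth `alpha = 2*pi*frac(m*phi1)` and polar angle
#' `beta = arccos(frac(m*phi2))`; the direction is
#' `(sin(beta) cos(alpha), sin(beta) sin(alpha), cos(beta))`. The fractional
#' part is taken before the trigonometric functions so `arccos` is defined;
#' directions lie on the upper hemisphere (`z >= 0`), which covers the full
#' sphere because each spoke is acquired as a full diameter through the
#' k-space origin.
#'
#' @param m Positive integer spoke index (vectorized).
#' @return A `length(m)` x 3 matrix of unit vectors.
#' @export
spoke_direction <- function(m) {
  if (any(m < 1)) stop("spoke index `m` must be >= 1")
  gm <- golden_means()
  az <- 2 * pi * ((m * gm[["phi1"]]) %% 1)
  cb <- (m * gm[["phi2"]]) %% 1
  sb <- sqrt(pmax(0, 1 - cb^2))
  cbind(x = sb * cos(az), y = sb * sin(az), z = cb)
}

#' Build the k-space sampling pattern of a full acquisition
#'
#' Generates the golden-ratio radial spokes of `n_timepoints * n_repeats`
#' readouts with repeat-first ordering: the global spoke index of
#' timepoint `i`, repeat `j` is `m(i, j) = (i - 1) * n_repeats + j`, so the
#' repeat index advances fastest and each timepoint's spokes form a
#' contiguous golden-ratio run (approximately uniform on the sphere).
#' Each spoke is a full diameter: `samples_per_spoke` positions uniformly
#' spaced from `-kmax` to `+kmax * (1 - 2/samples_per_spoke)` along the
#' spoke direction, with `kmax = 0.5` cycles/voxel.
#'
#' @param n_timepoints Number of readouts (frames) per repeat.
#' @param n_repeats Number of preparation repeats.
#' @param matrix_size Reconstruction matrix size (voxels per dimension).
#' @param samples_per_spoke Readout samples per spoke (default
#'   `2 * matrix_size`, a two-fold oversampled readout).
#' @return An object of class `kspace_sampling`: list with
#'   `coords` (`n_spokes` x `samples_per_spoke` x 3 array, cycles/voxel),
#'   `directions` (`n_spokes` x 3), `assignment` (`n_timepoints` x
#'   `n_repeats` matrix of global spoke indices), `timepoint_of_spoke`
#'   (length `n_spokes`), and the scalar geometry fields.
#' @export
build_sampling <- function(n_timepoints, n_repeats, matrix_size,
                           samples_per_spoke = 2L * matrix_size) {
  stopifnot(n_timepoints >= 1, n_repeats >= 1, matrix_size >= 1,
            samples_per_spoke >= 1)
  n_timepoints <- as.integer(n_timepoints)
  n_repeats <- as.integer(n_repeats)
  samples_per_spoke <- as.integer(samples_per_spoke)
  n_spokes <- n_timepoints * n_repeats
  dirs <- spoke_direction(seq_len(n_spokes))
  kmax <- 0.5
  radii <- seq(-kmax, kmax - 2 * kmax / samples_per_spoke,
               length.out = samples_per_spoke)
  coords <- array(0, dim = c(n_spokes, samples_per_spoke, 3L))
  for (d in 1:3) coords[, , d] <- outer(dirs[, d], radii)
  assignment <- matrix(seq_len(n_spokes), nrow = n_timepoints,
                       ncol = n_repeats, byrow = TRUE)
  structure(
    list(
      coords = coords,
      directions = dirs,
      assignment = assignment,
      timepoint_of_spoke = rep(seq_len(n_timepoints), each = n_repeats),
      n_timepoints = n_timepoints,
      n_repeats = n_repeats,
      matrix_size = as.integer(matrix_size),
      samples_per_spoke = samples_per_spoke
    ),
    class = "kspace_sampling"
  )
}

#' @export
print.kspace_sampling <- function(x, ...) {
  cat(sprintf(
    "kspace_sampling: %d timepoints x %d repeats = %d spokes, %d samples/spoke, matrix %d^3\n",
    x$n_timepoints, x$n_repeats, nrow(x$directions), x$samples_per_spoke,
    x$matrix_size))
  invisible(x)
}

#' Temporal binning of readouts into frames
#'
#' Groups the `n_timepoints` one-TR readouts into contiguous,
#' non-overlapping bins of `bin_size` adjacent timepoints (the last bin is
#' truncated when `bin_size` does not divide `n_timepoints`). The center
#' post-labeling delay of bin `b` is
#' `((b - 1) * bin_size + bin_size / 2) * tr`, the middle of its temporal
#' window measured from the end of labeling.
#'
#' @param n_timepoints Number of one-TR readouts.
#' @param bin_size Timepoints per bin (<= `n_timepoints`).
#' @param tr Repetition time in seconds (used only for the center PLDs;
#'   optional).
#' @return A data frame with one row per bin: `frame`, `first`, `last`
#'   (timepoint indices) and, when `tr` is given, `center_pld` in seconds.
#' @export
bin_frames <- function(n_timepoints, bin_size, tr = NULL) {
  stopifnot(n_timepoints >= 1, bin_size >= 1)
  if (bin_size > n_timepoints) stop("`bin_size` must not exceed `n_timepoints`")
  first <- seq(1L, n_timepoints, by = bin_size)
  last <- pmin(first + bin_size - 1L, n_timepoints)
  out <- data.frame(frame = seq_along(first), first = first, last = last)
  if (!is.null(tr)) {
    out$center_pld <- ((out$frame - 1) * bin_size + bin_size / 2) * tr
  }
  out
}
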