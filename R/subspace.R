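#' Physiological parameter grid for dictionary generation
#'
#' Cartesian product of linearly spaced values (endpoints inclusive) of
#' transit time, sharpness and time-to-peak. The amplitude is excluded
#' (fixed at 1): a global scaling does not change the subspace. The default
#' ranges and 40 samples per axis give the standard 64000-entry grid.
#'
#' @param delta_t_range Transit-time range, seconds.
#' @param sharpness_range Sharpness range, 1/seconds.
#' @param time_to_peak_range Time-to-peak range, seconds.
#' @param n_per_axis Samples per parameter axis (>= 2).
#' @return A data frame with columns `delta_t`, `sharpness`,
#'   `time_to_peak`; time-to-peak varies fastest, transit time slowest.
#' @export
parameter_grid <- function(delta_t_range = c(0.1, 2.0),
                           sharpness_range = c(1, 20),
                           time_to_peak_range = c(0.001, 0.5),
                           n_per_axis = 40L) {
  check_range <- function(r, name) {
    if (length(r) != 2L || !is.numeric(r) || r[1] >= r[2])
      stop(sprintf("`%s` must be an increasing (min, max) pair", name))
  }
  check_range(delta_t_range, "delta_t_range")
  check_range(sharpness_range, "sharpness_range")
  check_range(time_to_peak_range, "time_to_peak_range")
  stopifnot(n_per_axis >= 2)
  lin <- function(r) seq(r[1], r[2], length.out = n_per_axis)
  g <- expand.grid(
    time_to_peak = lin(time_to_peak_range),
    sharpness = lin(sharpness_range),
    delta_t = lin(delta_t_range),
    KEEP.OUT.ATTRS = FALSE
  )
  g[, c("delta_t", "sharpness", "time_to_peak")]
}

#' Build a signal dictionary over a parameter grid
#'
#' Simulates one model timecourse per grid row (amplitude 1) with
#' [simulate_timecourses()]. Rows are not normalized: amplitude variation
#' across the grid weights the SVD basis. Optional row normalization is
#' available but off by default.
#'
#' @param grid A data frame from [parameter_grid()] (columns `delta_t`,
#'   `sharpness`, `time_to_peak`).
#' @param seq A [seq_params()] object.
#' @param normalize If `TRUE`, scale each row to unit L2 norm.
#' @return An object of class `signal_dictionary`: list with `x`
#'   (entries x timepoints matrix), `grid`, `seq`.
#' @export
build_dictionary <- function(grid, seq, normalize = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  x <- simulate_timecourses(grid, seq)
  if (normalize) {
    nrm <- sqrt(rowSums(x^2))
    nrm[nrm == 0] <- 1
    x <- x / nrm
  }
  structure(list(x = x, grid = grid, seq = seq),
            class = "signal_dictionary")
}

#' @export
print.signal_dictionary <- function(x, ...) {
  cat(sprintf("signal_dictionary: %d entries x %d timepoints\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

.dict_matrix <- function(dict) {
  if (inherits(dict, "signal_dictionary")) dict$x else as.matrix(dict)
}

.basis_matrix <- function(subspace) {
  if (inherits(subspace, "temporal_subspace")) subspace$basis
  else as.matrix(subspace)
}

#' Extract the temporal subspace of a dictionary
#'
#' Computes the singular value decomposition of the dictionary matrix
#' (entries x timepoints) and returns the first `k` right singular vectors
#' as the temporal basis. Column signs are fixed so that the
#' largest-magnitude element of each column is positive.
#'
#' @param dict A [build_dictionary()] object or a numeric matrix
#'   (entries x timepoints).
#' @param k Number of components to retain (1 <= k <= timepoints).
#' @return An object of class `temporal_subspace`: list with `basis`
#'   (timepoints x k, orthonormal columns), `singular_values` (all of
#'   them, non-increasing), `k`.
#' @export
extract_subspace <- function(dict, k = 12L) {
  x <- .dict_matrix(dict)
  n_t <- ncol(x)
  if (k < 1 || k > n_t) stop("`k` must be between 1 and the number of timepoints")
  sv <- svd(x, nu = 0, nv = n_t)
  basis <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    piv <- which.max(abs(basis[, j]))
    if (basis[piv, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(
    list(basis = basis, singular_values = sv$d, k = as.integer(k)),
    class = "temporal_subspace"
  )
}

#' @export
print.temporal_subspace <- function(x, ...) {
  cat(sprintf("temporal_subspace: %d timepoints, %d components\n",
              nrow(x$basis), x$k))
  ev <- cumsum(x$singular_values^2) / sum(x$singular_values^2)
  cat(sprintf("  energy captured by %d components: %.6f\n", x$k, ev[x$k]))
  invisible(x)
}

#' Frobenius relative approximation error of a dictionary
#'
#' `100 * ||X - X Phi Phi'||_F / ||X||_F`, the percentage of dictionary
#' signal energy (in the root-sum-of-squares sense) lost when every
#' timecourse is projected onto the temporal subspace.
#'
#' @param dict Dictionary object or entries x timepoints matrix.
#' @param subspace A `temporal_subspace` or a timepoints x k orthonormal
#'   basis matrix.
#' @return Relative error in percent.
#' @export
relative_error <- function(dict, subspace) {
  x <- .dict_matrix(dict)
  phi <- .basis_matrix(subspace)
  stopifnot(ncol(x) == nrow(phi))
  nx <- norm(x, "F")
  if (nx == 0) stop("dictionary has zero norm")
  resid <- x - (x %*% phi) %*% t(phi)
  100 * norm(resid, "F") / nx
}

#' Per-timepoint normalized RMS error of the subspace approximation
#'
#' For each timepoint (column), the root-mean-square residual of
#' `X - X Phi Phi'` across dictionary entries, divided by the RMS of the
#' original column. Columns with zero RMS report 0.
#'
#' @inheritParams relative_error
#' @return Numeric vector, one NRMSE per timepoint.
#' @export
nrmse_per_timepoint <- function(dict, subspace) {
  x <- .dict_matrix(dict)
  phi <- .basis_matrix(subspace)
  stopifnot(ncol(x) == nrow(phi))
  resid <- x - (x %*% phi) %*% t(phi)
  num <- sqrt(colMeans(resid^2))
  den <- sqrt(colMeans(x^2))
  out <- numeric(ncol(x))
  nz <- den > 0
  out[nz] <- num[nz] / den[nz]
  out
}

#' Expand subspace coefficients to the time domain
#'
#' Applies `x = Phi alpha` along the temporal dimension. Accepts a single
#' coefficient vector (length k), a k x voxels matrix, or a k-leading
#' array of coefficient maps; returns the corresponding timecourse,
#' timepoints x voxels matrix, or timepoints-leading array.
#'
#' @param coeffs Coefficients (vector, matrix or array with the component
#'   dimension first). May be complex.
#' @param subspace A `temporal_subspace` or basis matrix.
#' @return Expanded time series with the temporal dimension first.
#' @export
subspace_expand <- function(coeffs, subspace) {
  phi <- .basis_matrix(subspace)
  k <- ncol(phi)
  if (is.null(dim(coeffs))) {
    if (length(coeffs) != k) stop("coefficient length does not match basis")
    return(drop(phi %*% coeffs))
  }
  d <- dim(coeffs)
  if (d[1] != k) stop("first dimension of `coeffs` must match basis components")
  out <- phi %*% matrix(coeffs, nrow = k)
  if (length(d) > 2) dim(out) <- c(nrow(phi), d[-1])
  out
}

#' Project timecourses onto a temporal subspace
#'
#' Computes `alpha = Phi' x` (the least-squares coefficients for an
#' orthonormal basis). Temporal dimension first, matching
#' [subspace_expand()].
#'
#' @param x Timecourse vector, timepoints x voxels matrix, or
#'   timepoints-leading array.
#' @param subspace A `temporal_subspace` or basis matrix.
#' @return Coefficients with the component dimension first.
#' @export
subspace_project <- function(x, subspace) {
  phi <- .basis_matrix(subspace)
  if (is.null(dim(x))) {
    if (length(x) != nrow(phi)) stop("length of `x` does not match basis")
    return(drop(crossprod(phi, x)))
  }
  d <- dim(x)
  if (d[1] != nrow(phi)) stop("first dimension of `x` must match basis timepoints")
  out <- crossprod(phi, matrix(x, nrow = d[1]))
  if (length(d) > 2) dim(out) <- c(ncol(phi), d[-1])
  out
}
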