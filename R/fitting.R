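#' Default kinetic-parameter fit bounds
#'
#' Bounds for [refine_fit()], slightly exceeding the standard dictionary
#' ranges to avoid boundary pile-up: transit time 0.05-2.2 s, sharpness
#' 0.5-25 1/s, time-to-peak 0.001-0.6 s, amplitude >= 0.
#'
#' @return List with `lower` and `upper` named vectors over
#'   `(delta_t, sharpness, time_to_peak, amplitude)`.
#' @export
fit_bounds <- function() {
  list(
    lower = c(delta_t = 0.05, sharpness = 0.5, time_to_peak = 1e-3,
              amplitude = 0),
    upper = c(delta_t = 2.2, sharpness = 25, time_to_peak = 0.6,
              amplitude = Inf)
  )
}

#' Match a timecourse against a signal dictionary
#'
#' Returns the dictionary grid entry maximizing the normalized correlation
#' (cosine similarity) with the timecourse; the amplitude is set by
#' least-squares scaling against that (unit-amplitude) entry. Used to
#' initialize the nonlinear refinement.
#'
#' @param timecourse Numeric (or complex: magnitude is used) vector of
#'   length `n_readouts`.
#' @param dict A [build_dictionary()] object (unit amplitude entries).
#' @return A [kinetic_params()] object with an extra attribute
#'   `"match_index"` (the grid row), or `NULL` for an all-zero timecourse.
#' @export
dictionary_match <- function(timecourse, dict) {
  stopifnot(inherits(dict, "signal_dictionary"))
  y <- Mod(timecourse)
  if (all(y == 0)) return(NULL)
  x <- dict$x
  stopifnot(length(y) == ncol(x))
  rn <- sqrt(rowSums(x^2))
  ok <- rn > 0
  corr <- (x %*% y) / (pmax(rn, .Machine$double.xmin) * sqrt(sum(y^2)))
  corr[!ok] <- -Inf
  best <- which.max(corr)
  amp <- sum(x[best, ] * y) / sum(x[best, ]^2)
  out <- kinetic_params(
    delta_t = dict$grid$delta_t[best],
    sharpness = dict$grid$sharpness[best],
    time_to_peak = dict$grid$time_to_peak[best],
    amplitude = amp
  )
  attr(out, "match_index") <- best
  out
}

#' Bin-average a dictionary to a coarser temporal grid
#'
#' Averages each dictionary timecourse over contiguous bins of `bin_size`
#' timepoints, the forward model of a temporally binned acquisition.
#' Use the result to match or fit frames reconstructed by temporal
#' binning.
#'
#' @param dict A [build_dictionary()] object.
#' @param bin_size Timepoints per bin.
#' @return A `signal_dictionary` whose matrix has one column per bin.
#' @export
bin_average_dictionary <- function(dict, bin_size) {
  stopifnot(inherits(dict, "signal_dictionary"))
  dict$x <- .bin_average(dict$x, bin_size)
  dict$bin_size <- as.integer(bin_size)
  dict
}

# Average matrix columns within contiguous bins of `bin_size` timepoints.
.bin_average <- function(x, bin_size) {
  bins <- bin_frames(ncol(x), bin_size)
  out <- matrix(0, nrow(x), nrow(bins))
  for (b in seq_len(nrow(bins))) {
    out[, b] <- rowMeans(x[, bins$first[b]:bins$last[b], drop = FALSE])
  }
  out
}

#' Refine a kinetic-parameter fit by bounded nonlinear least squares
#'
#' Minimizes the sum of squared differences between the model timecourse
#' and the (magnitude) data over `(delta_t, sharpness, time_to_peak,
#' amplitude)` within bounds, by Levenberg-Marquardt
#' ([minpack.lm::nls.lm]) starting from `init`. Deterministic given the
#' inputs.
#'
#' @param timecourse Vector of length `n_readouts` (complex allowed).
#' @param init A [kinetic_params()] initialization (within bounds).
#' @param seq A [seq_params()] object.
#' @param bounds Bounds list as from [fit_bounds()].
#' @param bin_size When fitting temporally binned frames, the number of
#'   timepoints per frame: the model timecourse is bin-averaged before
#'   comparison and `timecourse` must have one value per bin.
#' @return A [kinetic_params()] object with attributes `"residual_nrmse"`
#'   (root-mean-square residual over the root-mean-square signal),
#'   `"converged"` (logical), and `"info"` (optimizer status code).
#' @export
refine_fit <- function(timecourse, init, seq, bounds = fit_bounds(),
                       bin_size = NULL) {
  stopifnot(inherits(init, "kinetic_params"), inherits(seq, "seq_params"))
  y <- Mod(timecourse)
  if (is.null(bin_size)) {
    stopifnot(length(y) == seq$n_readouts)
  } else {
    stopifnot(length(y) == nrow(bin_frames(seq$n_readouts, bin_size)))
  }
  par0 <- c(delta_t = init$delta_t, sharpness = init$sharpness,
            time_to_peak = init$time_to_peak, amplitude = init$amplitude)
  par0 <- pmin(pmax(par0, bounds$lower), bounds$upper)
  resid_fn <- function(par) {
    tc <- simulate_timecourse(
      kinetic_params(par[1], par[2], par[3], max(par[4], 0)), seq)
    model <- if (is.null(bin_size)) tc$values else
      drop(.bin_average(matrix(tc$values, nrow = 1), bin_size))
    model - y
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    lower = bounds$lower, upper = bounds$upper,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  converged <- fit$info %in% 1:4
  par <- unname(if (converged) fit$par else par0)
  out <- kinetic_params(par[1], par[2], par[3], par[4])
  rms <- sqrt(mean(y^2))
  attr(out, "residual_nrmse") <-
    sqrt(mean(resid_fn(par)^2)) / (rms + .Machine$double.eps)
  attr(out, "converged") <- converged
  attr(out, "info") <- fit$info
  out
}

#' Voxelwise kinetic-parameter estimation over a volume
#'
#' Fits every voxel whose peak magnitude exceeds `mask_threshold` times
#' the 95th percentile of the peak map: dictionary matching provides the
#' initialization, followed by bounded nonlinear least squares (magnitude
#' fit). Other voxels are left unset.
#'
#' @param series An [image_series()], a complex `x,y,z,time` array, or a
#'   `recon_result` from [reconstruct_subspace()] (expanded internally).
#' @param seq A [seq_params()] object.
#' @param dict A [build_dictionary()] object for the initialization.
#' @param mask_threshold Fraction of the 95th-percentile peak signal below
#'   which voxels are not fit (default 0.2).
#' @param refine Run the nonlinear refinement (default `TRUE`); otherwise
#'   the dictionary-match parameters are returned.
#' @param bounds Bounds list as from [fit_bounds()].
#' @param bin_size For temporally binned input (one frame per bin), the
#'   timepoints per bin; the dictionary and model are bin-averaged.
#' @param mask Optional explicit fit mask overriding the threshold rule: a
#'   logical 3D array, a vector of linear voxel indices, or an `n x 3`
#'   matrix of voxel coordinates (e.g. `vessel_phantom()$voxels`).
#' @return An object of class `parameter_maps`: list of 3D arrays
#'   `delta_t`, `sharpness`, `time_to_peak`, `amplitude`, `residual`
#'   (NRMSE) and logical `mask`; unfit voxels are `NA`.
#' @export
fit_volume <- function(series, seq, dict, mask_threshold = 0.2,
                       refine = TRUE, bounds = fit_bounds(),
                       bin_size = NULL, mask = NULL) {
  if (inherits(series, "recon_result")) {
    series <- if (series$mode == "subspace") expand_recon(series)$data
    else series$frames
  }
  if (inherits(series, "image_series")) series <- series$data
  if (is.null(bin_size)) {
    stopifnot(length(dim(series)) == 4L, dim(series)[4] == seq$n_readouts)
  } else {
    dict <- bin_average_dictionary(dict, bin_size)
    stopifnot(length(dim(series)) == 4L,
              dim(series)[4] == nrow(bin_frames(seq$n_readouts, bin_size)))
  }
  d <- dim(series)[1:3]
  mags <- Mod(matrix(series, nrow = prod(d))) # voxels x time
  peak <- apply(mags, 1, max)
  if (is.null(mask)) {
    ref <- stats::quantile(peak, 0.95, type = 1, names = FALSE)
    mask <- peak > mask_threshold * ref & peak > 0
  } else {
    if (is.matrix(mask) && ncol(mask) == 3L) {
      mask <- mask[, 1] + (mask[, 2] - 1) * d[1] + (mask[, 3] - 1) * d[1] * d[2]
    }
    if (!is.logical(mask)) {
      idx <- as.integer(mask)
      mask <- rep(FALSE, prod(d))
      mask[idx] <- TRUE
    }
    mask <- as.vector(mask) & peak > 0
  }
  blank <- array(NA_real_, dim = d)
  maps <- list(delta_t = blank, sharpness = blank, time_to_peak = blank,
               amplitude = blank, residual = blank,
               mask = array(mask, dim = d))
  for (v in which(mask)) {
    tc <- mags[v, ]
    init <- dictionary_match(tc, dict)
    if (is.null(init)) { maps$mask[v] <- FALSE; next }
    est <- if (refine) refine_fit(tc, init, seq, bounds, bin_size) else init
    maps$delta_t[v] <- est$delta_t
    maps$sharpness[v] <- est$sharpness
    maps$time_to_peak[v] <- est$time_to_peak
    maps$amplitude[v] <- est$amplitude
    maps$residual[v] <- if (refine) attr(est, "residual_nrmse") else {
      tcm <- simulate_timecourse(est, seq)$values
      if (!is.null(bin_size))
        tcm <- drop(.bin_average(matrix(tcm, nrow = 1), bin_size))
      sqrt(mean((tcm - tc)^2)) / (sqrt(mean(tc^2)) + .Machine$double.eps)
    }
  }
  structure(maps, class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("parameter_maps: %s volume, %d voxels fit\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask)))
  invisible(x)
}

#' Extract fitted parameters along the phantom vessel
#'
#' Convenience accessor returning a data frame of fitted parameters (and
#' ground truth) at the vessel voxels of a [vessel_phantom()].
#'
#' @param maps A [fit_volume()] result.
#' @param phantom The [vessel_phantom()] the volume was simulated from.
#' @return Data frame with columns `position`, fitted `delta_t`,
#'   `sharpness`, `time_to_peak`, `amplitude`, `residual`, `mask` and the
#'   ground-truth columns prefixed `true_`.
#' @export
vessel_fit_table <- function(maps, phantom) {
  stopifnot(inherits(maps, "parameter_maps"),
            inherits(phantom, "vessel_phantom"))
  vox <- phantom$voxels
  data.frame(
    position = seq_len(nrow(vox)),
    delta_t = maps$delta_t[vox],
    sharpness = maps$sharpness[vox],
    time_to_peak = maps$time_to_peak[vox],
    amplitude = maps$amplitude[vox],
    residual = maps$residual[vox],
    mask = maps$mask[vox],
    true_delta_t = phantom$params$delta_t,
    true_sharpness = phantom$params$sharpness,
    true_time_to_peak = phantom$params$time_to_peak,
    true_amplitude = phantom$params$amplitude
  )
}
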