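#' @useDynLib subangio, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Kaiser-Bessel kernel on [0, 1] of its half-width, normalized to 1 at 0.
.kb_kernel <- function(d_rel, beta) {
  out <- numeric(length(d_rel))
  inside <- abs(d_rel) < 1
  arg <- beta * sqrt(1 - d_rel[inside]^2)
  out[inside] <- besselI(arg, 0) / besselI(beta, 0)
  out
}

# Continuous Fourier transform of the width-W kernel, evaluated by Simpson
# quadrature (the integrand is smooth): used for the apodization correction.
.kb_transform <- function(x, width, beta, n_nodes = 2001L) {
  d <- seq(-width / 2, width / 2, length.out = n_nodes)
  h <- d[2] - d[1]
  w <- rep(c(2, 4), length.out = n_nodes)
  w[1] <- 1; w[n_nodes] <- 1
  phi <- .kb_kernel(d / (width / 2), beta)
  vapply(x, function(xi) sum(w * phi * cos(2 * pi * xi * d)) * h / 3,
         numeric(1))
}

#' Plan a 3D non-uniform FFT
#'
#' Precomputes the Kaiser-Bessel gridding machinery for evaluating the
#' non-uniform discrete Fourier transform
#' `y(k) = sum_j x[j] exp(-2i pi k . (j - c))` of an `n^3` image at
#' arbitrary k-space coordinates (cycles/voxel, DC at 0, `c = floor(n/2)`
#' the center voxel), and its exact adjoint. Uses a `oversamp`-times
#' oversampled FFT grid, a width-`width` Kaiser-Bessel interpolation kernel
#' with the Beatty shape parameter, and an apodization correction computed
#' by numerical quadrature of the kernel's continuous Fourier transform.
#'
#' @param matrix_size Image matrix size `n` (cubic volume).
#' @param coords Sample coordinates: an `m` x 3 matrix (or
#'   `spokes x samples x 3` array) in cycles/voxel, within `[-0.5, 0.5)`.
#' @param oversamp Grid oversampling factor (default 2).
#' @param width Kernel width in oversampled-grid cells (default 6).
#' @return An object of class `nufft_plan`.
#' @export
nufft_plan <- function(matrix_size, coords, oversamp = 2, width = 6L) {
  n <- as.integer(matrix_size)
  stopifnot(n >= 2)
  if (length(dim(coords)) == 3L) coords <- matrix(coords, ncol = 3L)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, all(is.finite(coords)),
            max(abs(coords)) <= 0.5 + 1e-12)
  g <- as.integer(round(oversamp * n))
  if (g %% 2L == 1L) g <- g + 1L
  sigma <- g / n
  width <- as.integer(width)
  beta <- pi * sqrt(width^2 / sigma^2 * (sigma - 0.5)^2 - 0.8)
  ntab <- 4096L
  table <- .kb_kernel(seq(0, 1, length.out = ntab), beta)
  cen <- n %/% 2L
  apod <- .kb_transform(((0:(n - 1)) - cen) / g, width, beta)
  apod3 <- outer(outer(apod, apod), apod)
  dim(apod3) <- c(n, n, n)
  qidx <- ((0:(n - 1)) - cen) %% g + 1L
  structure(
    list(
      n = n, g = g, width = width, beta = beta,
      table = table, apod3 = apod3, qidx = qidx,
      pts = coords * g, n_samples = nrow(coords)
    ),
    class = "nufft_plan"
  )
}

#' @export
print.nufft_plan <- function(x, ...) {
  cat(sprintf(
    "nufft_plan: %d^3 image -> %d samples (grid %d^3, kernel width %d)\n",
    x$n, x$n_samples, x$g, x$width))
  invisible(x)
}

#' Apply a non-uniform FFT plan
#'
#' `nufft_forward()` evaluates the Fourier transform of `image` at the
#' planned sample coordinates; `nufft_adjoint()` applies the exact adjoint
#' (conjugate-transpose) operator to a vector of samples. The pair passes
#' the inner-product adjoint test to machine precision; `nufft_adjoint` is
#' not an inverse.
#'
#' @param plan A [nufft_plan()].
#' @param image Complex (or real) `n^3` array.
#' @param subset Optional integer vector restricting the operation to a
#'   subset of the planned sample indices.
#' @return `nufft_forward`: complex vector of samples;
#'   `nufft_adjoint`: complex `n^3` array.
#' @export
nufft_forward <- function(plan, image, subset = NULL) {
  stopifnot(inherits(plan, "nufft_plan"))
  n <- plan$n
  if (is.null(dim(image))) dim(image) <- c(n, n, n)
  stopifnot(all(dim(image) == n))
  z <- array(0i, dim = c(plan$g, plan$g, plan$g))
  z[plan$qidx, plan$qidx, plan$qidx] <- image / plan$apod3
  zf <- stats::fft(z)
  pts <- if (is.null(subset)) plan$pts else plan$pts[subset, , drop = FALSE]
  kb_interpolate(zf, rep(plan$g, 3L), pts, plan$width, plan$table)
}

#' @rdname nufft_forward
#' @param values Complex sample vector (length = planned samples, or
#'   `length(subset)`).
#' @export
nufft_adjoint <- function(plan, values, subset = NULL) {
  stopifnot(inherits(plan, "nufft_plan"))
  pts <- if (is.null(subset)) plan$pts else plan$pts[subset, , drop = FALSE]
  stopifnot(length(values) == nrow(pts))
  zs <- kb_spread(as.complex(values), rep(plan$g, 3L), pts,
                  plan$width, plan$table)
  dim(zs) <- c(plan$g, plan$g, plan$g)
  zi <- stats::fft(zs, inverse = TRUE)
  zi[plan$qidx, plan$qidx, plan$qidx] / plan$apod3
}

#' Radial density-compensation weights
#'
#' Per-sample weights proportional to `|k|^2` (the Jacobian of 3D radial
#' sampling), with the DC sample given the weight of half the first radial
#' step. Used only to form initial estimates and low-resolution coil
#' images; the iterative reconstructions use the uncompensated operator.
#'
#' @param coords Sample coordinates (`m` x 3 matrix or
#'   `spokes x samples x 3` array), cycles/voxel.
#' @return Numeric weight vector normalized to mean 1.
#' @export
radial_dcf <- function(coords) {
  if (length(dim(coords)) == 3L) coords <- matrix(coords, ncol = 3L)
  r <- sqrt(rowSums(coords^2))
  pos <- r[r > 0]
  w <- pmax(r, if (length(pos)) min(pos) / 2 else 1)^2
  w / mean(w)
}
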