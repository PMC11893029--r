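#' Write or read a complex array as raw binary with a JSON header
#'
#' Arrays are stored losslessly as little-endian float64 with real and
#' imaginary parts interleaved, column-major, alongside a `.json` header
#' recording shape and dtype. This is the on-disk format for k-space data
#' and other complex arrays in run bundles.
#'
#' @param x Numeric or complex array.
#' @param path Output path for the binary payload (header written to
#'   `paste0(path, ".json")`).
#' @return `write_carray()`: `path`, invisibly. `read_carray()`: the
#'   array with its original shape and type.
#' @export
write_carray <- function(x, path) {
  is_cplx <- is.complex(x)
  hdr <- list(
    shape = if (is.null(dim(x))) length(x) else dim(x),
    dtype = if (is_cplx) "complex128" else "float64",
    order = "F",
    byte_order = "little"
  )
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  if (is_cplx) {
    inter <- as.vector(rbind(Re(as.vector(x)), Im(as.vector(x))))
    writeBin(inter, con, size = 8, endian = "little")
  } else {
    writeBin(as.double(as.vector(x)), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_carray
#' @export
read_carray <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(hdr$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  if (identical(hdr$dtype, "complex128")) {
    raw <- readBin(con, "double", n = 2 * n, size = 8, endian = "little")
    x <- complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
  } else {
    x <- readBin(con, "double", n = n, size = 8, endian = "little")
  }
  if (length(hdr$shape) > 1) dim(x) <- hdr$shape
  x
}

#' Write an image series or volume as NIfTI
#'
#' 4D series are written as magnitude volumes (NIfTI-1 has no complex
#' double type) with the voxel size in mm and the frame spacing (seconds)
#' in the 4th pixdim slot; complex data round-trips losslessly through
#' run bundles instead (see [write_carray()]).
#'
#' @param x An [image_series()], 4D array, or 3D array (e.g. a parameter
#'   map).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_mm Voxel size, mm (taken from an `image_series` input).
#' @param time_step_s Frame spacing in seconds for 4D data.
#' @return `path`, invisibly.
#' @export
write_nifti_series <- function(x, path, voxel_mm = 1.13, time_step_s = NULL) {
  if (inherits(x, "image_series")) {
    voxel_mm <- x$voxel_mm
    if (is.null(time_step_s) && length(x$time) > 1)
      time_step_s <- x$time[2] - x$time[1]
    x <- x$data
  }
  if (is.complex(x)) x <- Mod(x)
  nd <- length(dim(x))
  pixdim <- c(rep(voxel_mm, 3), if (nd == 4L) time_step_s %||% 1)
  img <- RNifti::asNifti(x, pixdim = pixdim)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_series
#' @export
read_nifti_series <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save or load a reproducible run bundle
#'
#' A run bundle is a directory holding the arrays and configuration of a
#' simulation/reconstruction run in open formats (YAML sequence config,
#' raw binary + JSON for complex arrays, CSV for tables) plus a
#' `manifest.json` with md5 checksums and provenance (package version,
#' seeds, timestamp). `load_run_bundle()` verifies every checksum and
#' errors naming any missing or corrupted file. Sampling geometry is
#' stored as its generating parameters and rebuilt deterministically on
#' load, so round-trips are bit-identical.
#'
#' @param path Bundle directory (created if needed).
#' @param seq A [seq_params()] object (required).
#' @param sampling Optional [build_sampling()] object.
#' @param kspace Optional `kspace_data`.
#' @param subspace Optional `temporal_subspace`.
#' @param series Optional [image_series()].
#' @param phantom Optional [vessel_phantom()].
#' @param extra Optional named list of small JSON-serializable metadata.
#' @return `save_run_bundle()`: `path` invisibly; `load_run_bundle()`: a
#'   named list with the stored components.
#' @export
save_run_bundle <- function(path, seq, sampling = NULL, kspace = NULL,
                            subspace = NULL, series = NULL, phantom = NULL,
                            extra = NULL) {
  stopifnot(inherits(seq, "seq_params"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  add <- function(f) files <<- c(files, f)
  write_seq_config(seq, file.path(path, "sequence.yaml")); add("sequence.yaml")
  meta <- list(package = "subangio",
               version = as.character(utils::packageVersion("subangio")),
               created = format(Sys.time(), tz = "UTC", usetz = TRUE))
  if (!is.null(sampling)) {
    stopifnot(inherits(sampling, "kspace_sampling"))
    jsonlite::write_json(
      sampling[c("n_timepoints", "n_repeats", "matrix_size",
                 "samples_per_spoke")],
      file.path(path, "sampling.json"), auto_unbox = TRUE)
    add("sampling.json")
  }
  if (!is.null(kspace)) {
    stopifnot(inherits(kspace, "kspace_data"))
    write_carray(kspace$data, file.path(path, "kspace.bin"))
    add("kspace.bin"); add("kspace.bin.json")
    meta$kspace <- list(noise_sigma = kspace$noise_sigma,
                        seed = kspace$seed,
                        scale_factor = kspace$scale_factor)
  }
  if (!is.null(subspace)) {
    stopifnot(inherits(subspace, "temporal_subspace"))
    write_carray(subspace$basis, file.path(path, "basis.bin"))
    write_carray(subspace$singular_values, file.path(path, "singular_values.bin"))
    add("basis.bin"); add("basis.bin.json")
    add("singular_values.bin"); add("singular_values.bin.json")
  }
  if (!is.null(series)) {
    stopifnot(inherits(series, "image_series"))
    write_carray(series$data, file.path(path, "series.bin"))
    add("series.bin"); add("series.bin.json")
    meta$series <- list(time = series$time, voxel_mm = series$voxel_mm)
  }
  if (!is.null(phantom)) {
    stopifnot(inherits(phantom, "vessel_phantom"))
    utils::write.csv(phantom$params, file.path(path, "phantom_params.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(matrix_size = phantom$matrix_size, axis = phantom$axis),
      file.path(path, "phantom.json"), auto_unbox = TRUE)
    add("phantom_params.csv"); add("phantom.json")
  }
  if (!is.null(extra)) meta$extra <- extra
  checksums <- as.list(tools::md5sum(file.path(path, files)))
  names(checksums) <- files
  manifest <- list(meta = meta, files = checksums)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_run_bundle
#' @export
load_run_bundle <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", path)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  for (f in names(manifest$files)) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("bundle file missing: ", f)
    sum_now <- unname(tools::md5sum(fp))
    if (!identical(sum_now, manifest$files[[f]]))
      stop("checksum mismatch for bundle file: ", f)
  }
  out <- list(seq = read_seq_config(file.path(path, "sequence.yaml")),
              meta = manifest$meta)
  if (file.exists(file.path(path, "sampling.json"))) {
    sj <- jsonlite::read_json(file.path(path, "sampling.json"),
                              simplifyVector = TRUE)
    out$sampling <- build_sampling(sj$n_timepoints, sj$n_repeats,
                                   sj$matrix_size, sj$samples_per_spoke)
  }
  if (file.exists(file.path(path, "kspace.bin"))) {
    ks <- manifest$meta$kspace
    out$kspace <- structure(
      list(data = read_carray(file.path(path, "kspace.bin")),
           noise_sigma = ks$noise_sigma %||% 0,
           seed = ks$seed,
           scale_factor = ks$scale_factor %||% 1),
      class = "kspace_data")
  }
  if (file.exists(file.path(path, "basis.bin"))) {
    basis <- read_carray(file.path(path, "basis.bin"))
    sv <- read_carray(file.path(path, "singular_values.bin"))
    out$subspace <- structure(
      list(basis = basis, singular_values = as.vector(sv),
           k = ncol(basis)),
      class = "temporal_subspace")
  }
  if (file.exists(file.path(path, "series.bin"))) {
    sm <- manifest$meta$series
    out$series <- image_series(read_carray(file.path(path, "series.bin")),
                               time = sm$time, voxel_mm = sm$voxel_mm)
  }
  if (file.exists(file.path(path, "phantom.json"))) {
    pj <- jsonlite::read_json(file.path(path, "phantom.json"),
                              simplifyVector = TRUE)
    pp <- utils::read.csv(file.path(path, "phantom_params.csv"))
    ph <- vessel_phantom(pj$matrix_size, axis = pj$axis)
    ph$params <- pp
    out$phantom <- ph
  }
  out
}

#' Write parameter maps as NIfTI volumes
#'
#' One volume per fitted parameter (`delta_t`, `sharpness`,
#' `time_to_peak`, `amplitude`, `residual`) plus the fit `mask`; unfit
#' voxels are NaN.
#'
#' @param maps A [fit_volume()] result.
#' @param dir Output directory.
#' @param voxel_mm Voxel size, mm.
#' @return The directory, invisibly.
#' @export
write_parameter_maps <- function(maps, dir, voxel_mm = 1.13) {
  stopifnot(inherits(maps, "parameter_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("delta_t", "sharpness", "time_to_peak", "amplitude",
               "residual")) {
    write_nifti_series(maps[[nm]], file.path(dir, paste0(nm, ".nii.gz")),
                       voxel_mm = voxel_mm)
  }
  write_nifti_series(maps$mask + 0, file.path(dir, "mask.nii.gz"),
                     voxel_mm = voxel_mm)
  invisible(dir)
}
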