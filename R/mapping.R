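#' Multi-echo volume container
#'
#' A 4D (x, y, z, echo) magnitude image with its echo times and spatial
#' metadata.
#'
#' @param data 4D numeric array; 4th dimension indexes echoes.
#' @param echo_times Echo times (ms), one per 4th-dimension slab.
#' @param voxel_size Voxel dimensions in mm (length 3).
#' @param affine 4x4 voxel-to-world transform.
#' @return An object of class \code{"multiecho_volume"}.
#' @export
multiecho_volume <- function(data, echo_times,
                             voxel_size = c(1, 1, 1), affine = diag(4)) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] == length(echo_times),
            all(diff(echo_times) > 0), length(voxel_size) == 3L,
            all(dim(affine) == c(4, 4)))
  if (any(data < 0)) stop("magnitude data must be non-negative")
  structure(list(data = data, echo_times = as.numeric(echo_times),
                 voxel_size = as.numeric(voxel_size), affine = affine),
            class = "multiecho_volume")
}

#' @export
print.multiecho_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Multi-echo volume %dx%dx%d, %d echoes (TE %g-%g ms)\n",
              d[1], d[2], d[3], d[4], min(x$echo_times), max(x$echo_times)))
  invisible(x)
}

#' Scalar map container
#'
#' A 3D parameter map (MWF, flip angle or misfit). Masked-out or invalid
#' voxels carry \code{NA} in memory; \code{\link{write_scalar_map}} encodes
#' them as 0 alongside a validity mask on disk.
#'
#' @param data 3D numeric array, \code{NA} where undefined.
#' @param affine 4x4 voxel-to-world transform.
#' @param units One of \code{"fraction"}, \code{"degrees"}, \code{"misfit"}.
#' @return An object of class \code{"scalar_map"}.
#' @export
scalar_map <- function(data, affine = diag(4),
                       units = c("fraction", "degrees", "misfit")) {
  stopifnot(length(dim(data)) == 3L)
  units <- match.arg(units)
  structure(list(data = data, affine = affine, units = units),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  d <- dim(x$data)
  v <- x$data[!is.na(x$data)]
  cat(sprintf("Scalar map (%s) %dx%dx%d; %d valid voxels", x$units,
              d[1], d[2], d[3], length(v)))
  if (length(v)) cat(sprintf("; mean %.4g", mean(v)))
  cat("\n")
  invisible(x)
}

#' Erode a binary mask by one voxel
#'
#' One iteration of morphological erosion with a 6-connected (face
#' adjacent) structuring element: a voxel survives only if it and all six
#' face neighbours are inside the mask, so the output is always a subset of
#' the input and the outermost voxel shell is removed. Used to clean white
#' matter masks of brain-edge artifacts before ROI statistics.
#'
#' @param mask 3D array, strictly binary (0/1 or logical).
#' @return Logical 3D array of the same shape.
#' @export
erode_mask <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  if (!all(mask %in% c(0, 1)))
    stop("mask must be binary (0/1 or logical)")
  m <- array(mask != 0, dim(mask))
  d <- dim(m)
  shift <- function(axis, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by == 1L) { idx_dst[[axis]] <- 2:n;      idx_src[[axis]] <- 1:(n - 1) }
    else          { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  out <- m
  for (axis in 1:3) {
    if (d[axis] < 2) { out[] <- FALSE; next }
    out <- out & shift(axis, 1L) & shift(axis, -1L)
  }
  out
}

#' Fit every voxel of a masked multi-echo volume
#'
#' Applies \code{\link{fit_voxel}} independently to each in-mask voxel and
#' assembles MWF, flip-angle and misfit maps. Fitting is deterministic:
#' identical inputs give bit-identical maps, and voxel independence means
#' results on any sub-mask coincide with the restriction of a full-mask
#' run. The EPG decay dictionary for the candidate flip angles is computed
#' once and shared across voxels. Out-of-mask and invalid (sub-noise-floor)
#' voxels are \code{NA} in every map.
#'
#' @param vol A \code{\link{multiecho_volume}}.
#' @param mask 3D binary array matching the spatial dimensions.
#' @param config An \code{\link{mwf_config}}.
#' @param verbose Report progress every few hundred voxels.
#' @return An object of class \code{"mwf_maps"}: list of
#'   \code{\link{scalar_map}}s \code{mwf}, \code{flip_angle}, \code{chi2},
#'   plus the config used.
#' @export
fit_volume <- function(vol, mask, config = mwf_config(), verbose = FALSE) {
  stopifnot(inherits(vol, "multiecho_volume"))
  d <- dim(vol$data)
  if (!all(dim(mask) == d[1:3]))
    stop("mask shape does not match volume spatial dimensions")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  sq <- seq_params(echo_spacing = vol$echo_times[1],
                   n_echoes = length(vol$echo_times))
  if (!isTRUE(all.equal(echo_times(sq), vol$echo_times)))
    stop("echo times must be uniformly spaced starting at one echo spacing")
  bases <- lapply(config$angles, function(a) decay_basis(config$grid, a, sq))
  mwf <- flip <- chi2 <- array(NA_real_, d[1:3])
  idx <- which(mask != 0)
  nvox <- prod(d[1:3])
  for (ii in seq_along(idx)) {
    v <- idx[ii]
    sig <- vol$data[v + nvox * (seq_len(d[4]) - 1L)]
    fit <- fit_voxel(sig, sq, config, bases = bases)
    if (fit$valid) {
      mwf[v] <- fit$mwf
      flip[v] <- fit$flip_angle
      chi2[v] <- fit$chi2
    }
    if (verbose && ii %% 200L == 0L)
      message("fitted ", ii, " / ", length(idx), " voxels")
  }
  structure(list(mwf = scalar_map(mwf, vol$affine, "fraction"),
                 flip_angle = scalar_map(flip, vol$affine, "degrees"),
                 chi2 = scalar_map(chi2, vol$affine, "misfit"),
                 config = config),
            class = "mwf_maps")
}

#' @export
print.mwf_maps <- function(x, ...) {
  cat("MWF map set\n  ")
  print(x$mwf)
  cat("  ")
  print(x$flip_angle)
  invisible(x)
}

#' Mean of a scalar map over a region of interest
#'
#' Arithmetic mean over valid (non-missing) in-ROI voxels; missing voxels
#' are excluded from numerator and denominator. An ROI with no valid voxel
#' is an error, never silently zero.
#'
#' @param map A \code{\link{scalar_map}} (or a bare 3D array).
#' @param roi 3D binary array of the same shape.
#' @return Scalar mean.
#' @export
roi_mean <- function(map, roi) {
  data <- if (inherits(map, "scalar_map")) map$data else map
  stopifnot(length(dim(data)) == 3L)
  if (!all(dim(roi) == dim(data))) stop("ROI shape does not match map")
  if (!all(roi %in% c(0, 1))) stop("ROI must be binary")
  sel <- (roi != 0) & !is.na(data)
  if (!any(sel)) stop("ROI contains no valid voxels")
  mean(data[sel])
}

#' Read a 4D multi-echo NIfTI volume
#'
#' @param path NIfTI-1 file.
#' @param echo_times Echo times (ms) of the 4th dimension.
#' @return A \code{\link{multiecho_volume}}.
#' @export
read_multiecho_nifti <- function(path, echo_times) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  multiecho_volume(arr, echo_times,
                   voxel_size = RNifti::pixdim(img)[1:3],
                   affine = unclass(RNifti::xform(img)))
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI-1 file; any non-zero voxel is inside the mask.
#' @return Logical 3D array.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim(img)[1:3])
}

#' Write a scalar map (plus validity mask) to NIfTI
#'
#' Missing voxels are written as 0 and flagged 0 in a companion
#' \code{*_valid} mask, since many NIfTI viewers mishandle NaN.
#'
#' @param map A \code{\link{scalar_map}}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return Invisibly, the paths written (map and validity mask).
#' @export
write_scalar_map <- function(map, path) {
  stopifnot(inherits(map, "scalar_map"))
  valid <- !is.na(map$data)
  data <- map$data
  data[!valid] <- 0
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(map$affine, code = 2L))
  RNifti::writeNifti(img, path)
  vpath <- sub("(\\.nii(\\.gz)?)$", "_valid\\1", path)
  vimg <- RNifti::asNifti(array(as.numeric(valid), dim(valid)))
  vimg <- RNifti::`sform<-`(vimg, structure(map$affine, code = 2L))
  RNifti::writeNifti(vimg, vpath)
  invisible(c(map = path, valid = vpath))
}

#' Write all maps of a fitted volume
#'
#' @param maps An \code{"mwf_maps"} object from \code{\link{fit_volume}}.
#' @param prefix Output path prefix; writes \code{<prefix>mwf.nii.gz},
#'   \code{<prefix>flip.nii.gz}, \code{<prefix>chi2.nii.gz} and their
#'   validity masks.
#' @return Invisibly, the written paths.
#' @export
write_mwf_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "mwf_maps"))
  paths <- c(write_scalar_map(maps$mwf, paste0(prefix, "mwf.nii.gz")),
             write_scalar_map(maps$flip_angle, paste0(prefix, "flip.nii.gz")),
             write_scalar_map(maps$chi2, paste0(prefix, "chi2.nii.gz")))
  invisible(paths)
}
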