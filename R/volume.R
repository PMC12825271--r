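#' Image volume on a regular grid
#'
#' A `safconn_volume` is a 3D (or 4D, with repetitions along the 4th axis)
#' numeric array together with its physical geometry. The coordinate
#' convention throughout the package is voxel-center alignment with 0-based
#' indices: world mm = `origin_mm + index * voxel_size_mm` per axis. Grids are
#' axis-aligned; oblique affines are out of scope.
#'
#' @param data numeric 3D or 4D array.
#' @param voxel_size_mm positive numeric vector of length 3 (mm per voxel).
#' @param origin_mm numeric vector of length 3, world position of voxel
#'   (0,0,0)'s center.
#' @return An object of class `safconn_volume`.
#' @export
volume <- function(data, voxel_size_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) {
    stop("volume data must be a 3D or 4D array, got ", nd, " dimensions")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be 3 positive finite numbers")
  }
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm))) {
    stop("origin_mm must be 3 finite numbers")
  }
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, origin_mm = origin_mm),
    class = "safconn_volume"
  )
}

is_volume <- function(x) inherits(x, "safconn_volume")

#' @export
print.safconn_volume <- function(x, ...) {
  cat("<safconn_volume> ", paste(dim(x$data), collapse = " x "),
      " grid, voxel ", paste(signif(x$voxel_size_mm, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @rdname volume
#' @param x object to test / convert.
#' @export
as_volume <- function(x, voxel_size_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (is_volume(x)) return(x)
  volume(x, voxel_size_mm, origin_mm)
}

spatial_dim <- function(vol) dim(vol$data)[1:3]

#' Read / write volumes as NIfTI-1
#'
#' Volumes are stored as NIfTI-1 with the voxel size in `pixdim` and the
#' origin in the sform translation (axis-aligned diagonal sform).
#'
#' @param vol a [volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume_nifti` returns `path` invisibly; `read_volume_nifti`
#'   returns a [volume()].
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(is_volume(vol))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  aff <- diag(c(vol$voxel_size_mm, 1))
  aff[1:3, 4] <- vol$origin_mm
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vox <- abs(diag(aff)[1:3])
  if (all(vox == 0)) vox <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr)) # drop the niftiImage baggage
  volume(arr, voxel_size_mm = vox, origin_mm = aff[1:3, 4])
}

#' Mean of a map within a binary mask
#'
#' Arithmetic mean of voxel values over `mask > 0` voxels, e.g. mean FA
#' within a superficial white-matter mask.
#'
#' @param map3d a 3D [volume()] or numeric array.
#' @param mask 3D logical/numeric array (nonzero = inside), same spatial grid.
#' @return scalar mean.
#' @export
masked_mean <- function(map3d, mask) {
  arr <- if (is_volume(map3d)) map3d$data else as.array(map3d)
  mask <- as.array(mask)
  if (!identical(dim(arr)[1:3], dim(mask)[1:3]) || length(dim(arr)) != 3L) {
    stop("map and mask shapes do not match")
  }
  inside <- mask > 0
  if (!any(inside)) stop("mask is empty")
  mean(arr[inside])
}

#' Temporal signal-to-noise ratio of a b=0 series
#'
#' Per-voxel tSNR is the temporal mean divided by the temporal standard
#' deviation (sample SD, denominator n-1) across the 4th-axis repetitions.
#' The scalar summary is the arithmetic mean of per-voxel tSNR over mask
#' voxels with positive SD; zero-SD voxels are excluded and counted.
#'
#' @param series a 4D [volume()] or array (x, y, z, repetition).
#' @param mask 3D binary array matching the spatial grid.
#' @return list with `scalar` (mean tSNR in mask), `map` (per-voxel tSNR, NA
#'   outside mask and at zero-SD voxels), `n_voxels` used and
#'   `n_zero_sd` excluded.
#' @export
tsnr <- function(series, mask) {
  arr <- if (is_volume(series)) series$data else as.array(series)
  if (length(dim(arr)) != 4L) stop("series must be 4D (x, y, z, volume)")
  nvol <- dim(arr)[4]
  if (nvol < 2L) stop("need at least 2 volumes to estimate temporal SD")
  mask <- as.array(mask) > 0
  if (!identical(dim(mask), dim(arr)[1:3])) stop("mask shape does not match series")
  if (!any(mask)) stop("mask is empty")

  flat <- matrix(arr, nrow = prod(dim(arr)[1:3]), ncol = nvol)
  idx <- which(mask)
  mu <- rowMeans(flat[idx, , drop = FALSE])
  sd_ <- sqrt(rowSums((flat[idx, , drop = FALSE] - mu)^2) / (nvol - 1))
  ok <- sd_ > 0
  if (!any(ok)) {
    stop("temporal SD is zero at every mask voxel; tSNR undefined ",
         "(identical repetitions?)")
  }
  map <- array(NA_real_, dim(arr)[1:3])
  map[idx[ok]] <- mu[ok] / sd_[ok]
  list(scalar = mean(mu[ok] / sd_[ok]), map = map,
       n_voxels = sum(ok), n_zero_sd = sum(!ok))
}
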