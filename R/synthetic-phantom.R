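#' Band-limited cosine phantom volume
#'
#' A test image that is an exact finite sum of real 3D cosines on the grid:
#' `dc_level + sum_c amplitude_c * cos(2 pi k_c . x / N + phase_c)` with
#' integer frequency index `k_c` per axis and 0-based voxel index `x`. The
#' band limit is known by construction, which makes the phantom an analytic
#' oracle for k-space truncation and spline round trips.
#'
#' @param grid_shape 3 integers.
#' @param voxel_size_mm voxel size (default 1 mm).
#' @param components list of components, each a list with `freq` (3 integer
#'   frequency indices), `amplitude`, and optional `phase` (radians).
#' @param dc_level constant offset (default 0).
#' @return a [volume()].
#' @export
make_phantom_volume <- function(grid_shape, voxel_size_mm = 1,
                                components = list(), dc_level = 0) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  arr <- array(dc_level, grid_shape)
  ix <- seq_len(grid_shape[1]) - 1
  iy <- seq_len(grid_shape[2]) - 1
  iz <- seq_len(grid_shape[3]) - 1
  for (comp in components) {
    k <- as.numeric(comp$freq)
    if (length(k) != 3L || any(k != round(k))) {
      stop("component freq must be 3 integer indices")
    }
    if (any(abs(k) > grid_shape / 2)) {
      stop("frequency index ", paste(k, collapse = ","),
           " outside the representable range of the grid")
    }
    phase <- if (is.null(comp$phase)) 0 else comp$phase
    ph <- 2 * pi * (outer(outer(k[1] * ix / grid_shape[1],
                                k[2] * iy / grid_shape[2], "+"),
                          k[3] * iz / grid_shape[3], "+")) + phase
    arr <- arr + comp$amplitude * cos(ph)
  }
  volume(arr, rep_len(as.numeric(voxel_size_mm), 3L))
}

#' Noisy b=0 image series with a brain mask
#'
#' Each repetition is `mean_signal` plus i.i.d. Gaussian noise inside an
#' ellipsoidal "brain" mask (semi-axes 40% of the grid) and exactly zero
#' outside — the minimal signal model under which the temporal SNR
#' definition has a known answer (`mean_signal / noise_sd`).
#'
#' @param grid_shape 3 integers.
#' @param n_volumes number of repetitions (>= 2).
#' @param mean_signal true mean inside the mask.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed integer seed.
#' @param voxel_size_mm voxel size (default 1 mm).
#' @return list with `series` (4D [volume()]) and `mask` (3D logical array).
#' @export
make_b0_series <- function(grid_shape, n_volumes, mean_signal, noise_sd,
                           seed = 1L, voxel_size_mm = 1) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L)
  if (n_volumes < 2L) stop("need n_volumes >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ctr <- (grid_shape - 1) / 2
  semi <- pmax(0.4 * grid_shape, 1)
  ix <- (seq_len(grid_shape[1]) - 1 - ctr[1]) / semi[1]
  iy <- (seq_len(grid_shape[2]) - 1 - ctr[2]) / semi[2]
  iz <- (seq_len(grid_shape[3]) - 1 - ctr[3]) / semi[3]
  mask <- outer(outer(ix^2, iy^2, "+"), iz^2, "+") <= 1
  arr <- array(0, c(grid_shape, n_volumes))
  nin <- sum(mask)
  with_seed(seed, {
    for (v in seq_len(n_volumes)) {
      slab <- array(0, grid_shape)
      slab[mask] <- mean_signal + stats::rnorm(nin, 0, noise_sd)
      arr[, , , v] <- slab
    }
  })
  list(series = volume(arr, rep_len(as.numeric(voxel_size_mm), 3L)),
       mask = mask)
}
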