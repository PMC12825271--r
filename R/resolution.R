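#' Lower the spatial resolution of a volume by k-space truncation
#'
#' Retrospective resolution degradation: the centered 3D discrete Fourier
#' spectrum is truncated to the target matrix size and the retained
#' coefficients are multiplied by a separable Tukey taper (mild apodization
#' against Gibbs ringing). The taper has unit gain over the central
#' `1 - taper_fraction` of the retained band per axis, so low-frequency
#' content — including the image mean (DC) — passes unchanged. The field of
#' view is preserved: output voxel size is the input voxel size times
#' `source_shape / target_shape` per axis.
#'
#' When a retained axis length is even and smaller than the source length,
#' the unpaired Nyquist coefficient is zeroed so the truncated spectrum stays
#' conjugate-symmetric and the inverse transform real.
#'
#' @param vol a 3D (or 4D, processed volume-wise) [volume()].
#' @param target_shape integer vector of length 3, each entry no larger than
#'   the corresponding source dimension.
#' @param taper_fraction fraction in `[0, 1]` of the retained band tapered at
#'   each edge (default 0.2; 0 = hard truncation).
#' @return a [volume()] on the coarser grid.
#' @export
downsample_kspace <- function(vol, target_shape, taper_fraction = 0.2) {
  vol <- as_volume(vol)
  target_shape <- as.integer(round(target_shape))
  if (length(target_shape) != 3L || any(target_shape < 1L)) {
    stop("target_shape must be 3 positive integers")
  }
  src <- spatial_dim(vol)
  if (any(target_shape > src)) {
    stop("target_shape (", paste(target_shape, collapse = "x"),
         ") exceeds source shape (", paste(src, collapse = "x"),
         ") on at least one axis")
  }
  if (taper_fraction < 0 || taper_fraction > 1) {
    stop("taper_fraction must be in [0, 1]")
  }
  vox_out <- vol$voxel_size_mm * src / target_shape
  if (length(dim(vol$data)) == 4L) {
    out <- array(0, c(target_shape, dim(vol$data)[4]))
    for (v in seq_len(dim(vol$data)[4])) {
      out[, , , v] <- kspace_truncate_3d(vol$data[, , , v], target_shape, taper_fraction)
    }
    return(volume(out, vox_out, vol$origin_mm))
  }
  out <- kspace_truncate_3d(vol$data, target_shape, taper_fraction)
  volume(out, vox_out, vol$origin_mm)
}

# centered DFT indices for an axis of length n: -floor(n/2) .. ceil(n/2)-1
centered_freqs <- function(n) seq.int(-(n %/% 2), (n + 1) %/% 2 - 1)

# Tukey gain over retained centered frequencies k of a target axis length m:
# unit over |k|/(m/2) <= 1-a, cosine roll-off beyond.
tukey_gain <- function(k, m, a) {
  if (m == 1L) return(rep(1, length(k)))
  f <- abs(k) / (m / 2)
  w <- rep(1, length(k))
  if (a > 0) {
    roll <- f > (1 - a)
    w[roll] <- 0.5 * (1 + cos(pi * (f[roll] - (1 - a)) / a))
  }
  w
}

kspace_truncate_3d <- function(arr, m, a) {
  s <- dim(arr)
  F <- stats::fft(arr)
  sidx <- vector("list", 3L) # source DFT positions of the retained band
  tidx <- vector("list", 3L) # their DFT positions on the target grid
  wts <- vector("list", 3L)
  for (d in 1:3) {
    k <- centered_freqs(m[d])
    sidx[[d]] <- (k %% s[d]) + 1L
    tidx[[d]] <- (k %% m[d]) + 1L
    w <- tukey_gain(k, m[d], a)
    # unpaired Nyquist of a strictly truncated even axis breaks conjugate
    # symmetry; zero it
    if (m[d] %% 2L == 0L && m[d] < s[d]) w[k == -(m[d] %/% 2)] <- 0
    wts[[d]] <- w
  }
  Fsub <- F[sidx[[1]], sidx[[2]], sidx[[3]], drop = FALSE]
  dim(Fsub) <- m
  W <- outer(outer(wts[[1]], wts[[2]]), wts[[3]])
  dim(W) <- m
  G <- array(0i, m)
  G[tidx[[1]], tidx[[2]], tidx[[3]]] <- Fsub * W
  out <- stats::fft(G, inverse = TRUE) / prod(s)
  scale <- max(abs(out), 1e-300)
  if (max(abs(Im(out))) > 1e-10 * scale) {
    stop("inverse transform is not real (imaginary residual ",
         signif(max(abs(Im(out))) / scale, 3), "); internal symmetry error")
  }
  array(Re(out), m)
}

#' Up-sample a volume with polynomial B-spline interpolation
#'
#' Separable B-spline interpolation of order 0-5 (default cubic), with the
#' standard interpolation prefilter and mirror-reflected boundaries. The
#' sampling convention matches [downsample_kspace()]: index 0 of the source
#' and target grids coincide and the field of view is preserved, so target
#' position `j` samples the source at index `j * source_shape / target_shape`.
#' Constant volumes are reproduced exactly and orders >= 1 reproduce linear
#' ramps away from the boundary.
#'
#' @param vol a 3D (or 4D, processed volume-wise) [volume()].
#' @param target_shape integer vector of length 3, each entry at least the
#'   source dimension. Exactly one of `target_shape`/`target_voxel_size_mm`.
#' @param target_voxel_size_mm desired voxel size; converted to the nearest
#'   grid shape preserving the field of view.
#' @param spline_order integer in `[0, 5]`; 0 = nearest, 1 = linear,
#'   3 = cubic (default).
#' @param boundary `"mirror"` (default; reflected edges, suits real images)
#'   or `"periodic"` (wrap-around, the natural match for data produced by
#'   the periodic Fourier down-sampler, e.g. band-limited phantoms).
#' @return a [volume()] on the finer grid.
#' @export
upsample_spline <- function(vol, target_shape = NULL, target_voxel_size_mm = NULL,
                            spline_order = 3L, boundary = c("mirror", "periodic")) {
  boundary <- match.arg(boundary)
  vol <- as_volume(vol)
  if (spline_order < 0 || spline_order > 5 || spline_order != round(spline_order)) {
    stop("spline_order must be an integer in [0, 5]")
  }
  src <- spatial_dim(vol)
  if (is.null(target_shape) == is.null(target_voxel_size_mm)) {
    stop("give exactly one of target_shape or target_voxel_size_mm")
  }
  if (is.null(target_shape)) {
    tv <- rep_len(as.numeric(target_voxel_size_mm), 3L)
    if (any(tv <= 0)) stop("target_voxel_size_mm must be positive")
    target_shape <- as.integer(round(src * vol$voxel_size_mm / tv))
  }
  target_shape <- as.integer(round(target_shape))
  if (any(target_shape < src)) {
    stop("target grid must be at least as fine as the source on every axis")
  }
  vox_out <- vol$voxel_size_mm * src / target_shape

  interp3 <- function(arr) {
    for (d in 1:3) {
      pos <- seq_len(target_shape[d]) - 1
      pos <- pos * src[d] / target_shape[d]
      arr <- bspline_interp_axis(arr, d, pos, as.integer(spline_order), boundary)
    }
    arr
  }
  if (length(dim(vol$data)) == 4L) {
    out <- array(0, c(target_shape, dim(vol$data)[4]))
    for (v in seq_len(dim(vol$data)[4])) out[, , , v] <- interp3(vol$data[, , , v])
    return(volume(out, vox_out, vol$origin_mm))
  }
  volume(interp3(vol$data), vox_out, vol$origin_mm)
}

# --- B-spline internals (Unser-style prefilter + kernel evaluation) ---------

# centered B-spline kernel of integer order n, vectorized in x
bspline_kernel <- function(n, x) {
  if (n == 0L) return(as.numeric(x >= -0.5 & x < 0.5))
  ((x + (n + 1) / 2) * bspline_kernel(n - 1L, x + 0.5) +
     ((n + 1) / 2 - x) * bspline_kernel(n - 1L, x - 0.5)) / n
}

bspline_poles <- function(n) {
  switch(as.character(n),
    "2" = sqrt(8) - 3,
    "3" = sqrt(3) - 2,
    "4" = c(sqrt(664 - sqrt(438976)) + sqrt(304) - 19,
            sqrt(664 + sqrt(438976)) - sqrt(304) - 19),
    "5" = c(sqrt(135 / 2 - sqrt(17745 / 4)) + sqrt(105 / 4) - 13 / 2,
            sqrt(135 / 2 + sqrt(17745 / 4)) - sqrt(105 / 4) - 13 / 2),
    numeric(0))
}

# in-place recursive prefilter on the rows of matrix C (lines along rows),
# whole-sample mirror boundary
bspline_prefilter <- function(C, n) {
  poles <- bspline_poles(n)
  if (length(poles) == 0L) return(C)
  N <- nrow(C)
  if (N == 1L) return(C)
  gain <- prod((1 - poles) * (1 - 1 / poles))
  C <- C * gain
  for (z in poles) {
    # causal initialization (exact closed form under mirror symmetry when the
    # geometric horizon exceeds the line, truncated sum otherwise)
    horizon <- ceiling(log(1e-15) / log(abs(z)))
    if (horizon < N) {
      C[1, ] <- drop(z^(seq_len(horizon) - 1) %*% C[seq_len(horizon), , drop = FALSE])
    } else {
      zn <- z^(N - 1)
      s <- C[1, ] + zn * C[N, ]
      zn2 <- zn * zn / z
      for (k in 2:(N - 1)) {
        s <- s + (z^(k - 1) + zn2) * C[k, ]
        zn2 <- zn2 / z
      }
      C[1, ] <- s / (1 - z^(2 * N - 2))
    }
    for (k in 2:N) C[k, ] <- C[k, ] + z * C[k - 1, ]
    C[N, ] <- (z / (z * z - 1)) * (z * C[N - 1, ] + C[N, ])
    for (k in (N - 1):1) C[k, ] <- z * (C[k + 1, ] - C[k, ])
  }
  C
}

# exact periodic prefilter: deconvolve by the DFT of the sampled kernel
bspline_prefilter_periodic <- function(C, n) {
  if (n < 2L) return(C)
  N <- nrow(C)
  if (N == 1L) return(C)
  half <- (n %/% 2)
  kern <- rep(0, N)
  for (k in -half:half) {
    kern[(k %% N) + 1L] <- kern[(k %% N) + 1L] + bspline_kernel(n, k)
  }
  B <- Re(stats::fft(kern))
  Re(stats::mvfft(stats::mvfft(C) / B, inverse = TRUE)) / N
}

# reflect 1-based indices into [1, N] with period 2N-2 (mirror w/o repeat)
mirror_index <- function(i, N) {
  if (N == 1L) return(rep(1L, length(i)))
  p <- 2L * N - 2L
  j <- ((i - 1L) %% p + p) %% p
  j <- ifelse(j >= N, p - j, j)
  j + 1L
}

wrap_index <- function(i, N) ((i - 1L) %% N + N) %% N + 1L

# sparse-ish weight matrix mapping N coefficients to values at positions t
# (0-based source index units)
bspline_weights <- function(t, N, n, boundary = "mirror") {
  m <- length(t)
  W <- matrix(0, m, N)
  if (n == 0L) {
    # nearest neighbour, half-up so exact mid-grid points stay well defined
    cols <- floor(t + 0.5) + 1
    cols <- if (boundary == "periodic") wrap_index(as.integer(cols), N) else
      mirror_index(as.integer(cols), N)
    W[cbind(seq_len(m), cols)] <- 1
    return(W)
  }
  lo <- ceiling(t - (n + 1) / 2)
  for (j in 0:n) {
    k <- lo + j
    w <- bspline_kernel(n, t - k)
    cols <- if (boundary == "periodic") {
      wrap_index(as.integer(k) + 1L, N)
    } else {
      mirror_index(as.integer(k) + 1L, N)
    }
    W[cbind(seq_len(m), cols)] <- W[cbind(seq_len(m), cols)] + w
  }
  W
}

# interpolate a 3D array along one axis at the given 0-based positions
bspline_interp_axis <- function(arr, axis, positions, n, boundary = "mirror") {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  A <- aperm(arr, perm)
  N <- dim(A)[1]
  C <- matrix(A, nrow = N)
  C <- if (boundary == "periodic") {
    bspline_prefilter_periodic(C, n)
  } else {
    bspline_prefilter(C, n)
  }
  W <- bspline_weights(positions, N, n, boundary)
  out <- W %*% C
  dim(out) <- c(length(positions), dim(A)[2], dim(A)[3])
  aperm(out, order(perm))
}
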