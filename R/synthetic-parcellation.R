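# run code under a local RNG state so generators are pure functions of their
# seed and never disturb the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# deterministic child seeds below 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Synthetic cortical-ribbon parcellation with known adjacency
#'
#' Builds a test parcellation whose region adjacency is known analytically:
#' an annular "cortical ribbon" in a central axial slab, split into angular
#' wedges. Wedges on the negative-x side of the mid-sagittal plane form
#' hemisphere L, those on the positive side hemisphere R; a midline gap of
#' `midline_gap_mm` is carved out so no L voxel shares a face with an R
#' voxel. Within each hemisphere consecutive wedges border each other and
#' nothing else, so the true adjacency is a chain (not cyclic) of length
#' `n_regions_per_hemisphere`.
#'
#' Region ids are `1..n` (L, from the +y end of the half-annulus) and
#' `n+1..2n` (R); homologous wedges share a `name` (`wedge_1` ...) across
#' hemispheres.
#'
#' @param n_regions_per_hemisphere number of wedges per hemisphere (>= 2).
#' @param grid_shape 3 integers (default 40^3).
#' @param voxel_size_mm scalar or length-3 voxel size (default 1 mm).
#' @param inner_radius_mm,outer_radius_mm annulus radii (mm), outer > inner > 0.
#' @param midline_gap_mm total width of the excluded midline strip (mm).
#' @param slab_thickness_vox axial slab thickness in voxels.
#' @return list with `parcellation` (a [parcellation()]) and `adjacency`
#'   (the analytic chain adjacency, aligned to the region table).
#' @export
make_ribbon_parcellation <- function(n_regions_per_hemisphere,
                                     grid_shape = c(40L, 40L, 40L),
                                     voxel_size_mm = 1,
                                     inner_radius_mm = 12,
                                     outer_radius_mm = 18,
                                     midline_gap_mm = 2,
                                     slab_thickness_vox = 5L) {
  n <- as.integer(n_regions_per_hemisphere)
  if (n < 2L) stop("need at least 2 regions per hemisphere")
  if (!(outer_radius_mm > inner_radius_mm && inner_radius_mm > 0)) {
    stop("need outer_radius_mm > inner_radius_mm > 0")
  }
  grid_shape <- as.integer(grid_shape)
  vox <- rep_len(as.numeric(voxel_size_mm), 3L)
  half_fov <- (grid_shape - 1) * vox / 2
  if (any(half_fov[1:2] < outer_radius_mm)) {
    stop("grid too small to contain the annulus (half-FOV ",
         paste(signif(half_fov[1:2], 4), collapse = "x"), " mm < outer radius)")
  }
  center <- (grid_shape - 1) / 2 * vox  # world mm, origin at voxel (0,0,0)

  zc <- (grid_shape[3] - 1L) %/% 2L
  z_lo <- zc - (slab_thickness_vox - 1L) %/% 2L
  z_hi <- z_lo + slab_thickness_vox - 1L
  if (z_lo < 0L || z_hi >= grid_shape[3]) stop("slab exceeds the grid")

  x <- (seq_len(grid_shape[1]) - 1) * vox[1] - center[1]
  y <- (seq_len(grid_shape[2]) - 1) * vox[2] - center[2]
  dx <- matrix(x, grid_shape[1], grid_shape[2])
  dy <- matrix(y, grid_shape[1], grid_shape[2], byrow = TRUE)
  r <- sqrt(dx^2 + dy^2)
  in_ring <- r >= inner_radius_mm & r <= outer_radius_mm &
    abs(dx) >= midline_gap_mm / 2

  theta <- atan2(dy, dx)                      # (-pi, pi]
  slice <- matrix(0L, grid_shape[1], grid_shape[2])
  width <- pi / n
  # L hemisphere (dx < 0): phi in (pi/2, 3pi/2), wedge 1 at the +y end
  phi <- ifelse(theta >= 0, theta, theta + 2 * pi)
  wL <- pmin(pmax(floor((phi - pi / 2) / width) + 1, 1), n)
  # R hemisphere (dx > 0): theta in (-pi/2, pi/2), wedge 1 at the +y end
  wR <- pmin(pmax(floor((pi / 2 - theta) / width) + 1, 1), n)
  left <- in_ring & dx < 0
  right <- in_ring & dx > 0
  slice[left] <- as.integer(wL[left])
  slice[right] <- as.integer(n + wR[right])

  labels <- array(0L, grid_shape)
  for (z in z_lo:z_hi) labels[, , z + 1L] <- slice

  regions <- data.frame(
    id = 1:(2L * n),
    name = rep(paste0("wedge_", seq_len(n)), 2L),
    hemisphere = rep(c("L", "R"), each = n),
    stringsAsFactors = FALSE
  )
  counts <- tabulate(labels, nbins = 2L * n)
  if (any(counts == 0L)) {
    empty <- regions[counts == 0L, ]
    stop("geometry produced empty region(s): ",
         paste(paste0(empty$hemisphere, ":", empty$name), collapse = ", "))
  }
  parc <- parcellation(labels, regions, vox, origin_mm = c(0, 0, 0))

  A <- matrix(0L, 2L * n, 2L * n, dimnames = list(regions$id, regions$id))
  for (w in seq_len(n - 1L)) {
    A[w, w + 1L] <- A[w + 1L, w] <- 1L
    A[n + w, n + w + 1L] <- A[n + w + 1L, n + w] <- 1L
  }
  out <- list(parcellation = parc,
              adjacency = structure(A, class = c("safconn_adjacency", class(A))))
  attr(out, "geometry") <- list(inner_radius_mm = inner_radius_mm,
                                outer_radius_mm = outer_radius_mm,
                                center_mm = center)
  out
}
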