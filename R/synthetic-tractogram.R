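# evaluate a quadratic Bezier A -> C -> B and resample it at (approximately)
# uniform arc-length spacing
bezier_polyline <- function(A, C, B, spacing_mm, n_dense = 256L) {
  t <- seq(0, 1, length.out = n_dense)
  P <- outer((1 - t)^2, A) + outer(2 * t * (1 - t), C) + outer(t^2, B)
  seg <- sqrt(rowSums(diff(P)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  m <- max(2L, ceiling(L / spacing_mm) + 1L)
  s <- seq(0, L, length.out = m)
  tt <- stats::approx(cum, t, xout = s, ties = "ordered")$y
  out <- outer((1 - tt)^2, A) + outer(2 * tt * (1 - tt), C) + outer(tt^2, B)
  out[1, ] <- A   # endpoints exact
  out[m, ] <- B
  out
}

#' Synthetic U-fiber / long-fiber tractogram with known endpoint labels
#'
#' Generates streamlines on a [make_ribbon_parcellation()] geometry with
#' fully known ground truth. Short-range streamlines are U-shaped quadratic
#' Bezier arcs between adjacent wedges whose control point is displaced
#' radially inward to `u_depth_mm` below the ribbon's inner surface (the
#' classic sub-cortical U-arch); long-range streamlines between non-adjacent
#' same-hemisphere wedges route through the annulus interior. Every endpoint
#' is a jittered voxel center strictly inside its labelled voxel, so
#' containing-voxel endpoint assignment recovers the ground-truth labels
#' exactly.
#'
#' @param ribbon result of [make_ribbon_parcellation()].
#' @param short_pairs data.frame (`region_i`, `region_j`, `count`) of
#'   adjacent same-hemisphere pairs.
#' @param long_pairs data.frame of non-adjacent same-hemisphere pairs.
#' @param weight_mode `"unit"` (all weights 1) or `"lognormal"`
#'   (meanlog 0, sdlog 0.25 — SIFT-like weight spread).
#' @param point_spacing_mm polyline resampling step (default 1 mm).
#' @param jitter_mm endpoint jitter amplitude; clamped below half a voxel so
#'   endpoints stay inside their voxel.
#' @param u_depth_mm control-point depth below the ribbon inner surface (mm).
#' @param seed integer seed; identical inputs give bit-identical output.
#' @return list with `tractogram` (a [tractogram()]) and `truth`
#'   (data.frame `region_i`, `region_j`, `kind` per streamline).
#' @export
make_tractogram <- function(ribbon, short_pairs = NULL, long_pairs = NULL,
                            weight_mode = c("unit", "lognormal"),
                            point_spacing_mm = 1, jitter_mm = 0.2,
                            u_depth_mm = 3, seed = 1L) {
  weight_mode <- match.arg(weight_mode)
  parc <- ribbon$parcellation
  A <- ribbon$adjacency
  regions <- parc$regions
  vox <- parc$voxel_size_mm
  jit <- min(jitter_mm, 0.45 * min(vox))
  grid_shape <- dim(parc$labels)
  center <- (grid_shape - 1) / 2 * vox + parc$origin_mm
  geom <- attr(ribbon, "geometry")
  inner_r <- if (!is.null(geom)) geom$inner_radius_mm else {
    # infer the inner radius from the labelled voxels
    idx <- which(parc$labels > 0L, arr.ind = TRUE)
    mm <- sweep(sweep(idx - 1, 2L, vox, "*"), 2L, parc$origin_mm, "+")
    min(sqrt((mm[, 1] - center[1])^2 + (mm[, 2] - center[2])^2))
  }

  norm_pairs <- function(df, kind) {
    if (is.null(df) || nrow(df) == 0L) {
      return(data.frame(region_i = integer(0), region_j = integer(0),
                        count = integer(0), kind = character(0)))
    }
    stopifnot(all(c("region_i", "region_j", "count") %in% names(df)))
    if (any(df$count < 0)) stop("streamline counts must be >= 0")
    hi <- regions$hemisphere[match(df$region_i, regions$id)]
    hj <- regions$hemisphere[match(df$region_j, regions$id)]
    if (any(is.na(hi) | is.na(hj))) stop("unknown region id in ", kind, " pairs")
    if (any(hi != hj)) {
      bad <- which(hi != hj)[1]
      stop(kind, " pair (", df$region_i[bad], ", ", df$region_j[bad],
           ") is not same-hemisphere")
    }
    ii <- match(df$region_i, regions$id)
    jj <- match(df$region_j, regions$id)
    adj <- A[cbind(ii, jj)] > 0
    if (kind == "short" && any(!adj)) {
      bad <- which(!adj)[1]
      stop("short pair (", df$region_i[bad], ", ", df$region_j[bad],
           ") is not adjacent in the parcellation")
    }
    if (kind == "long" && any(adj)) {
      bad <- which(adj)[1]
      stop("long pair (", df$region_i[bad], ", ", df$region_j[bad],
           ") is adjacent; use short_pairs")
    }
    data.frame(region_i = df$region_i, region_j = df$region_j,
               count = as.integer(df$count), kind = kind,
               stringsAsFactors = FALSE)
  }
  pairs <- rbind(norm_pairs(short_pairs, "short"), norm_pairs(long_pairs, "long"))

  region_voxels <- lapply(regions$id, function(id) {
    which(parc$labels == id, arr.ind = TRUE) # 1-based indices
  })
  names(region_voxels) <- regions$id

  with_seed(seed, {
    streamlines <- list()
    truth <- list()
    for (p in seq_len(nrow(pairs))) {
      vi <- region_voxels[[as.character(pairs$region_i[p])]]
      vj <- region_voxels[[as.character(pairs$region_j[p])]]
      for (k in seq_len(pairs$count[p])) {
        pick <- function(vmat) {
          row <- vmat[sample.int(nrow(vmat), 1L), ]
          ctr <- (row - 1) * vox + parc$origin_mm
          ctr + stats::runif(3, -jit, jit)
        }
        Apt <- pick(vi)
        Bpt <- pick(vj)
        mid <- (Apt + Bpt) / 2
        dirxy <- mid[1:2] - center[1:2]
        r_mid <- sqrt(sum(dirxy^2))
        dirxy <- if (r_mid < 1e-9) c(1, 0) else dirxy / r_mid
        # place the control so the curve apex (0.5 r_mid + 0.5 r_C) sits at
        # the target radius; long fibers aim much deeper than U-fibers
        target <- if (pairs$kind[p] == "short") {
          max(inner_r - u_depth_mm, 0.5)
        } else {
          0.4 * inner_r
        }
        r_c <- 2 * target - r_mid
        Cpt <- c(center[1:2] + dirxy * r_c, mid[3])
        streamlines[[length(streamlines) + 1L]] <-
          bezier_polyline(Apt, Cpt, Bpt, point_spacing_mm)
        truth[[length(truth) + 1L]] <- c(pairs$region_i[p], pairs$region_j[p])
      }
    }
    ns <- length(streamlines)
    weights <- if (weight_mode == "unit") rep(1.0, ns) else {
      stats::rlnorm(ns, meanlog = 0, sdlog = 0.25)
    }
    truth_df <- if (ns) {
      tm <- do.call(rbind, truth)
      data.frame(region_i = tm[, 1], region_j = tm[, 2],
                 kind = rep(pairs$kind, pairs$count), stringsAsFactors = FALSE)
    } else {
      data.frame(region_i = integer(0), region_j = integer(0),
                 kind = character(0))
    }
    list(tractogram = tractogram(streamlines, weights), truth = truth_df)
  })
}
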