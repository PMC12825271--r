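#' Assign streamline endpoints to parcellation regions
#'
#' Each endpoint (first and last point of a streamline) maps to the label of
#' its containing voxel under voxel-center alignment. If that voxel is
#' background or outside the grid, the nearest labelled voxel center within
#' `search_radius_mm` (Euclidean) is used instead, mirroring the radial
#' endpoint search of standard connectome tooling; ties go to the lowest
#' region id. Otherwise the endpoint is unassigned (NA).
#'
#' @param tg a [tractogram()].
#' @param parc a [parcellation()] in the same world frame.
#' @param search_radius_mm fallback search radius in mm (default 2).
#' @return data.frame with one row per streamline: `region_i`, `region_j`
#'   (region ids or NA).
#' @export
assign_endpoints <- function(tg, parc, search_radius_mm = 2) {
  stopifnot(inherits(tg, "safconn_tractogram"),
            inherits(parc, "safconn_parcellation"))
  ns <- length(tg$streamlines)
  if (ns == 0L) {
    return(data.frame(region_i = integer(0), region_j = integer(0)))
  }
  ends <- matrix(0, 2L * ns, 3L)
  for (k in seq_len(ns)) {
    s <- tg$streamlines[[k]]
    ends[2L * k - 1L, ] <- s[1L, ]
    ends[2L * k, ] <- s[nrow(s), ]
  }
  lab <- assign_points_to_labels(ends, parc, search_radius_mm)
  data.frame(region_i = lab[seq(1L, 2L * ns, by = 2L)],
             region_j = lab[seq(2L, 2L * ns, by = 2L)])
}

# points: m x 3 world mm -> region id or NA
assign_points_to_labels <- function(points, parc, radius) {
  d <- dim(parc$labels)
  vox <- parc$voxel_size_mm
  org <- parc$origin_mm
  idx <- sweep(sweep(points, 2L, org), 2L, vox, "/") # 0-based fractional index
  near <- round(idx)
  out <- rep(NA_integer_, nrow(points))
  inb <- near[, 1] >= 0 & near[, 1] < d[1] &
         near[, 2] >= 0 & near[, 2] < d[2] &
         near[, 3] >= 0 & near[, 3] < d[3]
  flat <- near[, 1] + d[1] * (near[, 2] + d[2] * near[, 3]) + 1
  hit <- inb
  hit[inb] <- parc$labels[flat[inb]] > 0L
  out[hit] <- parc$labels[flat[hit]]

  todo <- which(!hit)
  if (length(todo) && radius > 0) {
    span <- ceiling(radius / vox)
    offs <- as.matrix(expand.grid(-span[1]:span[1], -span[2]:span[2],
                                  -span[3]:span[3]))
    for (p in todo) {
      cand <- sweep(offs, 2L, as.numeric(near[p, ]), "+")
      ok <- cand[, 1] >= 0 & cand[, 1] < d[1] &
            cand[, 2] >= 0 & cand[, 2] < d[2] &
            cand[, 3] >= 0 & cand[, 3] < d[3]
      if (!any(ok)) next
      cand <- cand[ok, , drop = FALSE]
      lv <- parc$labels[cand[, 1] + d[1] * (cand[, 2] + d[2] * cand[, 3]) + 1]
      lab_ok <- lv > 0L
      if (!any(lab_ok)) next
      cand <- cand[lab_ok, , drop = FALSE]
      lv <- lv[lab_ok]
      centers <- sweep(sweep(cand, 2L, vox, "*"), 2L, org, "+")
      dist <- sqrt(rowSums(sweep(centers, 2L, points[p, ])^2))
      within <- dist <= radius
      if (!any(within)) next
      dmin <- min(dist[within])
      best <- lv[within & dist <= dmin + 1e-12]
      out[p] <- min(best) # deterministic tie-break: lowest region id
    }
  }
  out
}

#' Build the association-fiber connectivity matrix
#'
#' Accumulates per-streamline weights into a symmetric region-by-region
#' strength matrix W. A streamline contributes only if both endpoints are
#' assigned and lie in the same hemisphere (commissural-like streamlines are
#' excluded, as are projection-like ones with an unassigned endpoint);
#' intra-regional streamlines (i = j) go to the diagonal once — only when
#' `include_intra` — otherwise they are dropped. With unit weights entries
#' are plain streamline counts (NOS).
#'
#' When `length_threshold_mm` is set, a companion `saf_numerator` matrix
#' accumulates only streamlines no longer than the threshold, so a
#' connection counts as short-range iff it is adjacent AND short. With
#' `threshold_scope = "both"` long streamlines are removed from W itself as
#' well.
#'
#' @param assignments data.frame from [assign_endpoints()] (region ids or NA).
#' @param lengths per-streamline lengths in mm (see [tractogram_lengths()]).
#' @param weights per-streamline positive weights.
#' @param regions region table as in [parcellation()].
#' @param include_intra keep intra-regional streamlines on the diagonal.
#' @param length_threshold_mm optional SAF length threshold (e.g. 50).
#' @param threshold_scope `"numerator"` (default) restricts only the
#'   short-range numerator; `"both"` also drops long streamlines from W.
#' @return object of class `safconn_connectivity`: list with `w`,
#'   `saf_numerator` (or NULL), `regions`, variant flags and a `report` of
#'   exclusion counts.
#' @export
build_connectivity <- function(assignments, lengths, weights, regions,
                               include_intra = FALSE,
                               length_threshold_mm = NULL,
                               threshold_scope = c("numerator", "both")) {
  threshold_scope <- match.arg(threshold_scope)
  ns <- nrow(assignments)
  if (length(lengths) != ns || length(weights) != ns) {
    stop("assignments, lengths and weights must be aligned")
  }
  ids <- regions$id
  n <- length(ids)
  known <- c(NA, ids)
  bad <- setdiff(unique(c(assignments$region_i, assignments$region_j)), known)
  if (length(bad)) {
    stop("region ids in assignments absent from region table: ",
         paste(sort(bad), collapse = ", "))
  }
  hemi <- regions$hemisphere[match(ids, ids)]
  hi <- regions$hemisphere[match(assignments$region_i, ids)]
  hj <- regions$hemisphere[match(assignments$region_j, ids)]

  unassigned <- is.na(assignments$region_i) | is.na(assignments$region_j)
  cross <- !unassigned & hi != hj
  intra <- !unassigned & !cross & assignments$region_i == assignments$region_j
  keep <- !unassigned & !cross & (include_intra | !intra)
  long_excluded <- 0L
  if (!is.null(length_threshold_mm) && threshold_scope == "both") {
    long <- keep & lengths > length_threshold_mm
    long_excluded <- sum(long)
    keep <- keep & !long
  }

  w <- matrix(0, n, n, dimnames = list(ids, ids))
  accumulate <- function(mask) {
    M <- matrix(0, n, n)
    if (any(mask)) {
      ii <- match(assignments$region_i[mask], ids)
      jj <- match(assignments$region_j[mask], ids)
      ww <- weights[mask]
      for (k in seq_along(ii)) {
        if (ii[k] == jj[k]) {
          M[ii[k], ii[k]] <- M[ii[k], ii[k]] + ww[k]
        } else {
          M[ii[k], jj[k]] <- M[ii[k], jj[k]] + ww[k]
          M[jj[k], ii[k]] <- M[jj[k], ii[k]] + ww[k]
        }
      }
    }
    dimnames(M) <- list(ids, ids)
    M
  }
  w <- accumulate(keep)
  saf_num <- NULL
  if (!is.null(length_threshold_mm)) {
    saf_num <- accumulate(keep & lengths <= length_threshold_mm)
  }
  structure(
    list(w = w, saf_numerator = saf_num, regions = regions,
         include_intra = include_intra,
         length_threshold_mm = length_threshold_mm,
         threshold_scope = threshold_scope,
         report = list(n_streamlines = ns,
                       n_retained = sum(keep),
                       n_unassigned = sum(unassigned),
                       n_commissural_like = sum(cross),
                       n_intra_dropped = sum(intra & !include_intra),
                       n_long_excluded = long_excluded)),
    class = "safconn_connectivity"
  )
}

#' @export
print.safconn_connectivity <- function(x, ...) {
  cat("<safconn_connectivity> ", nrow(x$w), " regions, total strength ",
      format(sum(x$w)), " (", x$report$n_retained, "/", x$report$n_streamlines,
      " streamlines retained)\n", sep = "")
  invisible(x)
}

#' One-call connectome from a tractogram and parcellation
#'
#' Convenience wrapper: endpoint assignment, length computation and matrix
#' accumulation in one step.
#'
#' @inheritParams assign_endpoints
#' @inheritParams build_connectivity
#' @return a `safconn_connectivity` (see [build_connectivity()]).
#' @export
connectome_from_tractogram <- function(tg, parc, search_radius_mm = 2,
                                       include_intra = FALSE,
                                       length_threshold_mm = NULL,
                                       threshold_scope = c("numerator", "both")) {
  assignments <- assign_endpoints(tg, parc, search_radius_mm)
  build_connectivity(assignments, tractogram_lengths(tg), tg$weights,
                     parc$regions, include_intra, length_threshold_mm,
                     threshold_scope)
}

#' Read / write connectivity matrices as TSV
#'
#' @param W a `safconn_connectivity` or plain matrix.
#' @param path TSV path (region ids as header row and first column).
#' @export
write_connectivity_tsv <- function(W, path) {
  M <- if (inherits(W, "safconn_connectivity")) W$w else as.matrix(W)
  write_matrix_tsv(M, path)
}

#' @rdname write_connectivity_tsv
#' @export
read_connectivity_tsv <- function(path) {
  read_matrix_tsv(path)
}
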