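#' Labelled cortical parcellation
#'
#' A `safconn_parcellation` couples a 3D non-negative integer label grid
#' (0 = background) with its physical geometry and a region table. The region
#' table has one row per region: `id` (positive integer, the grid value),
#' `name`, and `hemisphere` ("L" or "R"). Every nonzero grid value must
#' appear in the table.
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param regions data.frame with columns `id`, `name`, `hemisphere`.
#' @param voxel_size_mm,origin_mm grid geometry as in [volume()].
#' @return An object of class `safconn_parcellation`.
#' @export
parcellation <- function(labels, regions, voxel_size_mm = c(1, 1, 1),
                         origin_mm = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  needed <- c("id", "name", "hemisphere")
  if (!all(needed %in% names(regions))) {
    stop("region table needs columns: ", paste(needed, collapse = ", "))
  }
  regions$id <- as.integer(regions$id)
  if (anyDuplicated(regions$id)) stop("region ids must be unique")
  if (any(regions$id <= 0L)) stop("region ids must be positive")
  if (!all(regions$hemisphere %in% c("L", "R"))) {
    stop('hemisphere must be "L" or "R"')
  }
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, regions$id)
  if (length(missing)) {
    stop("labels present in grid but absent from region table: ",
         paste(sort(missing), collapse = ", "))
  }
  structure(
    list(labels = labels, regions = regions,
         voxel_size_mm = as.numeric(voxel_size_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "safconn_parcellation"
  )
}

#' @export
print.safconn_parcellation <- function(x, ...) {
  cat("<safconn_parcellation> ", nrow(x$regions), " regions on a ",
      paste(dim(x$labels), collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

#' Region adjacency ("borders-on") matrix from a labelled parcellation
#'
#' `A[i, j] = 1` iff regions i and j share at least `min_shared_faces`
#' 6-connected voxel faces in the label grid (and, by default, lie in the
#' same hemisphere — cross-hemisphere contact is ignored because association
#' connectomes zero cross-hemisphere entries anyway). The result is binary,
#' symmetric, zero-diagonal, and aligned to the region-table order with
#' region ids as dimnames.
#'
#' @param parc a [parcellation()].
#' @param min_shared_faces minimum number of touching voxel-face pairs
#'   (default 1).
#' @param within_hemisphere_only drop cross-hemisphere borders (default TRUE).
#' @return binary integer matrix of class `safconn_adjacency`.
#' @export
adjacency_from_labels <- function(parc, min_shared_faces = 1L,
                                  within_hemisphere_only = TRUE) {
  stopifnot(inherits(parc, "safconn_parcellation"))
  lab <- parc$labels
  ids <- parc$regions$id
  n <- length(ids)
  counts <- matrix(0, n, n, dimnames = list(ids, ids))
  pos <- match(seq_len(max(c(ids, 1L))), ids)  # label value -> region index

  tally <- function(a, b) {
    keep <- a != b & a > 0L & b > 0L
    if (!any(keep)) return(invisible(NULL))
    ia <- pos[a[keep]]; ib <- pos[b[keep]]
    t <- table(factor(pmin(ia, ib), levels = seq_len(n)),
               factor(pmax(ia, ib), levels = seq_len(n)))
    counts <<- counts + t + t(t)
    invisible(NULL)
  }
  d <- dim(lab)
  if (d[1] > 1L) tally(lab[-d[1], , , drop = FALSE], lab[-1, , , drop = FALSE])
  if (d[2] > 1L) tally(lab[, -d[2], , drop = FALSE], lab[, -1, , drop = FALSE])
  if (d[3] > 1L) tally(lab[, , -d[3], drop = FALSE], lab[, , -1, drop = FALSE])

  A <- (counts >= min_shared_faces) * 1L
  if (within_hemisphere_only) {
    same <- outer(parc$regions$hemisphere, parc$regions$hemisphere, "==")
    A <- A * (same * 1L)
  }
  diag(A) <- 0L
  structure(A, class = c("safconn_adjacency", class(A)))
}

#' Validate an adjacency matrix
#'
#' Checks symmetry, binarity, zero diagonal and (optionally) the
#' within-hemisphere restriction against a region table, erroring on the
#' first offending pair. Returns per-hemisphere counts of bordering pairs.
#'
#' @param A square binary matrix.
#' @param regions region table as in [parcellation()].
#' @param within_hemisphere_only if TRUE, any nonzero cross-hemisphere entry
#'   is an error.
#' @return list with `n_pairs_L`, `n_pairs_R`, `n_pairs_cross`, `n_pairs`.
#' @export
validate_adjacency <- function(A, regions, within_hemisphere_only = TRUE) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n != ncol(A) || n != nrow(regions)) {
    stop("adjacency must be square and aligned to the region table")
  }
  bad <- which(!A %in% c(0, 1))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(A))
    stop("non-binary entry at (", ij[1], ", ", ij[2], "): ", A[bad[1]])
  }
  dg <- which(diag(A) != 0)
  if (length(dg)) stop("nonzero diagonal at region ", regions$id[dg[1]])
  asym <- which(A != t(A))
  if (length(asym)) {
    ij <- arrayInd(asym[1], dim(A))
    stop("asymmetric at (", regions$id[ij[1]], ", ", regions$id[ij[2]], ")")
  }
  hemi <- regions$hemisphere
  cross <- outer(hemi, hemi, "!=") & A > 0
  if (within_hemisphere_only && any(cross)) {
    ij <- arrayInd(which(cross)[1], dim(A))
    stop("cross-hemisphere border between regions ", regions$id[ij[1]],
         " and ", regions$id[ij[2]])
  }
  up <- upper.tri(A) & A > 0
  list(
    n_pairs_L = sum(up & outer(hemi == "L", hemi == "L", "&")),
    n_pairs_R = sum(up & outer(hemi == "R", hemi == "R", "&")),
    n_pairs_cross = sum(up & outer(hemi, hemi, "!=")),
    n_pairs = sum(up)
  )
}

#' Read / write parcellations and adjacency matrices
#'
#' Parcellations are stored as a NIfTI-1 integer label volume plus a TSV
#' region table (columns `id`, `name`, `hemisphere`). Adjacency matrices are
#' TSV with region ids as header row and first column.
#'
#' @param parc a [parcellation()].
#' @param nifti_path,tsv_path output paths.
#' @return paths / objects, as appropriate.
#' @export
write_parcellation <- function(parc, nifti_path, tsv_path) {
  write_volume_nifti(volume(parc$labels + 0, parc$voxel_size_mm, parc$origin_mm),
                     nifti_path)
  utils::write.table(parc$regions, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nifti_path, tsv_path))
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(nifti_path, tsv_path) {
  vol <- read_volume_nifti(nifti_path)
  regions <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  parcellation(round(vol$data), regions, vol$voxel_size_mm, vol$origin_mm)
}

#' @rdname write_parcellation
#' @param A adjacency matrix.
#' @param path TSV path.
#' @export
write_adjacency_tsv <- function(A, path) {
  write_matrix_tsv(as.matrix(A) * 1L, path)
}

#' @rdname write_parcellation
#' @export
read_adjacency_tsv <- function(path) {
  M <- read_matrix_tsv(path)
  structure((M > 0) * 1L, dimnames = dimnames(M),
            class = c("safconn_adjacency", "matrix", "array"))
}
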