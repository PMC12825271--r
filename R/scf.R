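# helpers shared by the SCF metrics: pull the strength matrix, the
# short-range numerator matrix and the variant flags out of either a
# safconn_connectivity or a plain matrix
scf_parts <- function(W) {
  if (inherits(W, "safconn_connectivity")) {
    num <- if (!is.null(W$length_threshold_mm)) W$saf_numerator else W$w
    list(w = W$w, num = num, include_intra = isTRUE(W$include_intra))
  } else {
    M <- as.matrix(W)
    list(w = M, num = M, include_intra = FALSE)
  }
}

check_scf_shapes <- function(parts, A) {
  A <- as.matrix(A)
  if (!identical(dim(parts$w), dim(A))) {
    stop("connectivity and adjacency shapes differ: ",
         paste(dim(parts$w), collapse = "x"), " vs ",
         paste(dim(A), collapse = "x"))
  }
  A
}

#' Global Short-range Connectivity Fraction (GSCF)
#'
#' The fraction of total association connectivity strength carried by
#' short-range (adjacent-region) connections:
#' \deqn{GSCF = \sum_{i,j:\ A(i,j)=1} \omega_{i,j} \ / \ \sum_{i,j} \omega_{i,j}}
#' The double sums run over the full symmetric matrix exactly as written
#' (each pair counted twice); the ratio is unaffected. Normalising by total
#' strength makes GSCF invariant to global inflation of streamline counts,
#' so within-subject GSCF changes across acquisitions read as reconstruction
#' bias rather than count inflation.
#'
#' Variants carried by a `safconn_connectivity`: with `include_intra` the
#' diagonal strength is added to both numerator and denominator; with a
#' length threshold the numerator uses the `saf_numerator` matrix (adjacent
#' AND short).
#'
#' @param W a [build_connectivity()] result or plain symmetric nonnegative
#'   matrix aligned to `A`.
#' @param A binary adjacency matrix (see [adjacency_from_labels()]).
#' @return scalar in `[0, 1]`, or `NA` when total strength is 0 (undefined).
#' @export
gscf <- function(W, A) {
  parts <- scf_parts(W)
  A <- check_scf_shapes(parts, A)
  offA <- A > 0
  diag(offA) <- FALSE
  num <- sum(parts$num[offA])
  den <- sum(parts$w) - sum(diag(parts$w))
  if (parts$include_intra) {
    num <- num + sum(diag(parts$w))
    den <- den + sum(diag(parts$w))
  }
  if (den <= 0) return(NA_real_)
  num / den
}

#' Regional Short-range Connectivity Fraction (RSCF)
#'
#' For region k, the fraction of the connectivity strength originating from
#' k that is short-range:
#' \deqn{RSCF_k = \sum_{j:\ A(k,j)=1} \omega_{k,j} \ / \ \sum_j \omega_{k,j}}
#' Regions with zero total strength get `NA` (undefined) rather than 0: a
#' zero row is a data defect, not zero connectivity.
#'
#' @inheritParams gscf
#' @return named numeric vector (one value per region, `NA` where undefined).
#' @export
rscf <- function(W, A) {
  parts <- scf_parts(W)
  A <- check_scf_shapes(parts, A)
  offA <- A > 0
  diag(offA) <- FALSE
  num <- rowSums(parts$num * offA)
  den <- rowSums(parts$w) - diag(parts$w)
  if (parts$include_intra) {
    num <- num + diag(parts$w)
    den <- den + diag(parts$w)
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  nm <- rownames(parts$w)
  names(out) <- if (is.null(nm)) as.character(seq_along(out)) else nm
  out
}

#' Full SCF result (global + regional) for one connectome
#'
#' @inheritParams gscf
#' @return list of class `safconn_scf`: `gscf`, `rscf`, `undefined_regions`
#'   (region names/ids with zero strength) and the `variant` flags.
#' @export
scf_result <- function(W, A) {
  g <- gscf(W, A)
  r <- rscf(W, A)
  variant <- if (inherits(W, "safconn_connectivity")) {
    list(include_intra = isTRUE(W$include_intra),
         length_threshold_mm = W$length_threshold_mm)
  } else {
    list(include_intra = FALSE, length_threshold_mm = NULL)
  }
  structure(list(gscf = g, rscf = r,
                 undefined_regions = names(r)[is.na(r)],
                 variant = variant),
            class = "safconn_scf")
}

#' Relative SCF difference between conditions, in percent
#'
#' `100 * (scf_low - scf_high) / scf_high`: negative values mean the lower
#' resolution underestimates short-range connectivity relative to the higher
#' one.
#'
#' @param scf_low SCF at the lower-resolution (or comparison) condition.
#' @param scf_high SCF at the higher-resolution (reference) condition.
#' @return percent difference (vectorised); `NA` where `scf_high` is 0 or
#'   either input is undefined.
#' @export
relative_difference <- function(scf_low, scf_high) {
  out <- 100 * (scf_low - scf_high) / scf_high
  out[!is.na(scf_high) & scf_high == 0] <- NA_real_
  out
}

#' Group-level RSCF atlas
#'
#' Aggregates per-subject RSCF vectors into a per-region group mean and SD
#' (over subjects with defined values) plus a pooled histogram, the building
#' blocks of a group RSCF atlas.
#'
#' @param rscf_list list (one element per subject) of named RSCF vectors on
#'   a shared region table, e.g. from [rscf()].
#' @param breaks histogram bin edges over `[0, 1]` (default 20 equal bins).
#' @return list with `atlas` (data.frame: region, mean, sd, n_defined,
#'   n_undefined) and `histogram` (data.frame: bin_lo, bin_hi, count, pooled
#'   over all defined subject-region values).
#' @export
group_rscf_atlas <- function(rscf_list, breaks = seq(0, 1, by = 0.05)) {
  if (length(rscf_list) == 0L) stop("no subjects")
  M <- do.call(cbind, rscf_list) # regions x subjects
  if (is.null(rownames(M))) rownames(M) <- as.character(seq_len(nrow(M)))
  atlas <- data.frame(
    region = rownames(M),
    mean = apply(M, 1L, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)),
    sd = apply(M, 1L, function(v) if (sum(!is.na(v)) < 2L) NA_real_ else stats::sd(v, na.rm = TRUE)),
    n_defined = rowSums(!is.na(M)),
    n_undefined = rowSums(is.na(M)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  vals <- as.vector(M)
  vals <- vals[!is.na(vals)]
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  histogram <- data.frame(bin_lo = utils::head(h$breaks, -1),
                          bin_hi = h$breaks[-1], count = h$counts)
  list(atlas = atlas, histogram = histogram)
}
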