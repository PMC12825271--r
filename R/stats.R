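#' Paired within-subject comparison with a normality gate
#'
#' Implements the inference rule used throughout the package: differences
#' `d = x - y` are tested for normality with the Shapiro-Wilk test
#' (threshold `sw_alpha`); if not rejected, a two-sided paired t-test is
#' used, otherwise a two-sided Wilcoxon signed-rank test. Degenerate inputs
#' are handled explicitly: all-zero differences give `test_used =
#' "degenerate"` with p = 1; constant nonzero differences (Shapiro-Wilk
#' undefined) are routed to the Wilcoxon branch.
#'
#' Wilcoxon details: zero differences are dropped (classic signed-rank
#' convention; `zero_policy = "pratt"` keeps them in the ranking instead);
#' the exact null distribution is used for n <= 25 without tied `|d|`,
#' otherwise a normal approximation with continuity correction.
#'
#' @param x per-subject values under condition A (e.g. lower resolution).
#' @param y per-subject values under condition B (reference), same order.
#' @param sw_alpha Shapiro-Wilk gate threshold (default 0.05).
#' @param zero_policy `"drop"` (default) or `"pratt"` for zero differences
#'   in the Wilcoxon branch.
#' @param label optional label copied into the result.
#' @return list of class `safconn_paired`: `label`, `n` (pairs used),
#'   `normality_p`, `test_used` ("paired_t", "wilcoxon" or "degenerate"),
#'   `statistic`, `p_two_sided`, `mean_relative_difference_pct`
#'   (mean of `100 (x-y)/y`), and placeholders `p_fdr`/`significant` filled
#'   by the family-level functions.
#' @export
paired_compare <- function(x, y, sw_alpha = 0.05,
                           zero_policy = c("drop", "pratt"), label = NA_character_) {
  zero_policy <- match.arg(zero_policy)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs, got ", n)
  d <- x - y
  rel <- 100 * (x - y) / y
  mrd <- if (all(!is.finite(rel))) NA_real_ else mean(rel[is.finite(rel)])

  res <- list(label = label, n = n, normality_p = NA_real_,
              test_used = NA_character_, statistic = NA_real_,
              p_two_sided = NA_real_,
              mean_relative_difference_pct = mrd,
              p_fdr = NA_real_, significant = NA)
  if (all(d == 0)) {
    res$test_used <- "degenerate"
    res$p_two_sided <- 1.0
    return(structure(res, class = "safconn_paired"))
  }
  constant_d <- stats::sd(d) == 0
  if (!constant_d) {
    res$normality_p <- stats::shapiro.test(d)$p.value
  }
  if (!constant_d && res$normality_p >= sw_alpha) {
    tt <- stats::t.test(d, alternative = "two.sided")
    res$test_used <- "paired_t"
    res$statistic <- unname(tt$statistic)
    res$p_two_sided <- tt$p.value
  } else {
    w <- wilcoxon_signed_rank(d, zero_policy)
    res$test_used <- "wilcoxon"
    res$statistic <- w$statistic
    res$p_two_sided <- w$p.value
  }
  structure(res, class = "safconn_paired")
}

# two-sided signed-rank test; "drop" delegates to stats::wilcox.test with the
# spec's exact/approximate rule, "pratt" is a hand-rolled normal
# approximation that keeps zeros in the ranking
wilcoxon_signed_rank <- function(d, zero_policy) {
  if (zero_policy == "drop") {
    dnz <- d[d != 0]
    if (length(dnz) == 0L) return(list(statistic = NA_real_, p.value = 1.0))
    exact <- length(dnz) <= 25L && !any(duplicated(abs(dnz)))
    wt <- suppressWarnings(
      stats::wilcox.test(dnz, alternative = "two.sided", exact = exact,
                         correct = TRUE)
    )
    return(list(statistic = unname(wt$statistic), p.value = wt$p.value))
  }
  # Pratt: rank |d| including zeros, then discard zero ranks from W+
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  n0 <- sum(d == 0)
  EW <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  ties <- table(r[d != 0])
  VW <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  if (VW <= 0) return(list(statistic = W, p.value = 1.0))
  z <- (W - EW - sign(W - EW) * 0.5) / sqrt(VW)
  list(statistic = W, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`q_(i) = min_{j >= i} p_(j) m / j`, capped at
#' 1), returned in the original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] and be non-missing")
  }
  stats::p.adjust(p, method = "BH")
}

#' Cross-resolution GSCF comparisons within a method
#'
#' One paired comparison per unordered pair of conditions, with
#' Benjamini-Hochberg FDR correction across all pairs within each method.
#' `conditions` must be ordered from highest to lowest resolution; for a
#' pair the later (lower-resolution) condition plays `x` and the earlier
#' plays `y`, so negative relative differences mean the lower resolution
#' underestimates GSCF.
#'
#' @param df data.frame with columns `subject`, `condition`, `gscf` and
#'   optionally `method`.
#' @param conditions ordered condition labels (default: order of first
#'   appearance in `df`).
#' @param fdr_level significance threshold on FDR-adjusted p (default 0.05).
#' @param sw_alpha,zero_policy passed to [paired_compare()].
#' @return data.frame with one row per method x condition pair:
#'   all [paired_compare()] fields plus `method`, `cond_low`, `cond_high`.
#' @export
compare_gscf <- function(df, conditions = NULL, fdr_level = 0.05,
                         sw_alpha = 0.05, zero_policy = "drop") {
  if (!all(c("subject", "condition", "gscf") %in% names(df))) {
    stop("df needs columns subject, condition, gscf")
  }
  if (is.null(df$method)) df$method <- "method"
  if (is.null(conditions)) conditions <- unique(as.character(df$condition))
  unknown <- setdiff(unique(as.character(df$condition)), conditions)
  if (length(unknown)) stop("unknown condition label(s): ",
                            paste(unknown, collapse = ", "))
  if (length(conditions) < 2L) stop("need at least 2 conditions")
  pairs <- utils::combn(length(conditions), 2L)

  out <- list()
  for (m in unique(df$method)) {
    dm <- df[df$method == m, ]
    wide <- stats::reshape(
      dm[, c("subject", "condition", "gscf")],
      idvar = "subject", timevar = "condition", direction = "wide"
    )
    rows <- list()
    for (k in seq_len(ncol(pairs))) {
      hi <- conditions[pairs[1, k]]  # earlier = higher resolution
      lo <- conditions[pairs[2, k]]
      xv <- wide[[paste0("gscf.", lo)]]
      yv <- wide[[paste0("gscf.", hi)]]
      if (is.null(xv) || is.null(yv)) {
        stop("condition missing from data: ", if (is.null(xv)) lo else hi)
      }
      pc <- paired_compare(xv, yv, sw_alpha, zero_policy,
                           label = paste0(lo, " vs ", hi))
      rows[[k]] <- data.frame(
        method = m, cond_low = lo, cond_high = hi, n = pc$n,
        normality_p = pc$normality_p, test_used = pc$test_used,
        statistic = pc$statistic, p_two_sided = pc$p_two_sided,
        mean_relative_difference_pct = pc$mean_relative_difference_pct,
        stringsAsFactors = FALSE
      )
    }
    fam <- do.call(rbind, rows)
    fam$p_fdr <- bh_fdr(fam$p_two_sided)
    fam$significant <- fam$p_fdr < fdr_level
    out[[m]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-region RSCF comparison between two conditions
#'
#' Paired comparison of each region's RSCF at the lowest versus highest
#' resolution, with one Benjamini-Hochberg family across all tested regions.
#' Regions with fewer than 3 subjects having defined values in both
#' conditions are excluded and reported. Regions are classified
#' `"decrease"`, `"increase"` or `"none"` by the sign of the mean relative
#' difference and FDR significance.
#'
#' @param rscf_low,rscf_high region x subject matrices of RSCF values
#'   (rows aligned, NA = undefined).
#' @param fdr_level,sw_alpha,zero_policy as in [compare_gscf()].
#' @return list with `comparisons` (data.frame, one row per tested region)
#'   and `excluded_regions`.
#' @export
compare_rscf <- function(rscf_low, rscf_high, fdr_level = 0.05,
                         sw_alpha = 0.05, zero_policy = "drop") {
  rscf_low <- as.matrix(rscf_low); rscf_high <- as.matrix(rscf_high)
  if (!identical(dim(rscf_low), dim(rscf_high))) {
    stop("rscf_low and rscf_high must have identical shape")
  }
  regions <- rownames(rscf_low)
  if (is.null(regions)) regions <- as.character(seq_len(nrow(rscf_low)))
  testable <- rowSums(!is.na(rscf_low) & !is.na(rscf_high)) >= 3L
  rows <- list()
  for (k in which(testable)) {
    pc <- paired_compare(rscf_low[k, ], rscf_high[k, ], sw_alpha, zero_policy,
                         label = regions[k])
    rows[[length(rows) + 1L]] <- data.frame(
      region = regions[k], n = pc$n, normality_p = pc$normality_p,
      test_used = pc$test_used, statistic = pc$statistic,
      p_two_sided = pc$p_two_sided,
      mean_relative_difference_pct = pc$mean_relative_difference_pct,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no region has >= 3 complete subject pairs")
  cmp <- do.call(rbind, rows)
  cmp$p_fdr <- bh_fdr(cmp$p_two_sided)
  cmp$significant <- cmp$p_fdr < fdr_level
  cmp$direction <- ifelse(!cmp$significant, "none",
                          ifelse(cmp$mean_relative_difference_pct < 0,
                                 "decrease", "increase"))
  list(comparisons = cmp, excluded_regions = regions[!testable])
}

#' Top-10 RSCF-reduction frequency across methods
#'
#' For each method, regions are ranked by their signed RSCF difference
#' (most negative = largest reduction first); a region is a Top-10 member if
#' its rank is <= 10, with all regions tied at rank 10 included. The
#' frequency of Top-10 membership across methods is reported for regions at
#' or above `min_frequency` (default 50%), plus the homologous pairs —
#' region names whose left and right instances both survive the filter.
#'
#' @param diffs region x method matrix of signed RSCF differences (negative
#'   = reduction).
#' @param regions region table (`id`, `name`, `hemisphere`) aligned to the
#'   rows of `diffs`.
#' @param top_k rank cutoff (default 10).
#' @param min_frequency retention threshold on the membership frequency
#'   (default 0.5).
#' @return list with `frequency` (data.frame: region id/name/hemisphere,
#'   n_methods_in_top, frequency — filtered and sorted) and
#'   `homologous_pairs` (data.frame of names present for both hemispheres).
#' @export
top10_frequency <- function(diffs, regions, top_k = 10L, min_frequency = 0.5) {
  diffs <- as.matrix(diffs)
  if (nrow(diffs) != nrow(regions)) {
    stop("diffs rows must align with the region table")
  }
  n_methods <- ncol(diffs)
  if (n_methods < 1L) stop("need at least one method")
  member <- matrix(FALSE, nrow(diffs), n_methods)
  for (m in seq_len(n_methods)) {
    v <- diffs[, m]
    ok <- !is.na(v)
    if (sum(ok) <= top_k) {
      member[ok, m] <- TRUE   # fewer regions than the cutoff: all belong
      next
    }
    sorted <- sort(v[ok])     # ascending: most negative first
    cutoff <- sorted[top_k]   # ties at the cutoff are all included
    member[, m] <- ok & v <= cutoff
  }
  freq <- rowSums(member) / n_methods
  keep <- freq >= min_frequency
  tab <- data.frame(
    id = regions$id[keep], name = regions$name[keep],
    hemisphere = regions$hemisphere[keep],
    n_methods_in_top = rowSums(member)[keep], frequency = freq[keep],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$frequency, tab$name, tab$hemisphere), , drop = FALSE]
  rownames(tab) <- NULL
  both <- intersect(tab$name[tab$hemisphere == "L"],
                    tab$name[tab$hemisphere == "R"])
  homol <- tab[tab$name %in% both, , drop = FALSE]
  homol <- homol[order(homol$name, homol$hemisphere), , drop = FALSE]
  rownames(homol) <- NULL
  list(frequency = tab, homologous_pairs = homol)
}
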