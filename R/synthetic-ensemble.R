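#' Specification of a synthetic multi-resolution cohort
#'
#' Defines the paired within-subject study design the ensemble generator
#' emulates: `n_subjects` subjects, each measured at every resolution
#' condition; adjacent (short-range) pair strengths are attenuated by a
#' known per-condition factor `attenuation[r]` while non-adjacent
#' (long-range) pair strengths are unaffected; subjects carry a shared
#' multiplicative lognormal effect applied to all their conditions.
#'
#' @param n_subjects number of subjects (default 20).
#' @param n_regions_per_hemisphere regions per hemisphere, chain adjacency
#'   (default 5).
#' @param resolutions ordered condition labels, highest resolution first.
#' @param attenuation named vector mapping each condition to its
#'   short-range attenuation factor in (0, 1]; the first (reference)
#'   condition must have factor 1.
#' @param mean_short_count expected streamline count per adjacent pair at
#'   the reference resolution (default 200).
#' @param mean_long_count expected count per non-adjacent same-hemisphere
#'   pair (default 100).
#' @param subject_effect_sd SD of the log-scale subject multiplier
#'   (default 0.1).
#' @param noise_model `"poisson"` (counts drawn Poisson around their means)
#'   or `"none"` (means used directly).
#' @param seed root seed; per-subject/condition streams are derived from it.
#' @return validated list of class `safconn_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20L, n_regions_per_hemisphere = 5L,
                        resolutions = c("hi", "lo"),
                        attenuation = c(hi = 1, lo = 0.8),
                        mean_short_count = 200, mean_long_count = 100,
                        subject_effect_sd = 0.1,
                        noise_model = c("poisson", "none"), seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (n_subjects < 1L) stop("n_subjects must be positive")
  if (n_regions_per_hemisphere < 2L) stop("need >= 2 regions per hemisphere")
  if (length(resolutions) < 1L || anyDuplicated(resolutions)) {
    stop("resolutions must be distinct condition labels")
  }
  missing_cond <- setdiff(resolutions, names(attenuation))
  if (length(missing_cond)) {
    stop("condition label(s) missing from attenuation map: ",
         paste(missing_cond, collapse = ", "))
  }
  unknown <- setdiff(names(attenuation), resolutions)
  if (length(unknown)) {
    stop("unknown condition label(s) in attenuation map: ",
         paste(unknown, collapse = ", "))
  }
  a <- attenuation[resolutions]
  if (any(a <= 0 | a > 1)) stop("attenuation factors must lie in (0, 1]")
  if (a[[1]] != 1) stop("the reference (first) condition must have attenuation 1")
  if (mean_short_count <= 0) stop("mean_short_count must be > 0")
  if (mean_long_count < 0) stop("mean_long_count must be >= 0")
  if (subject_effect_sd < 0) stop("subject_effect_sd must be >= 0")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_regions_per_hemisphere = as.integer(n_regions_per_hemisphere),
    resolutions = as.character(resolutions), attenuation = a,
    mean_short_count = mean_short_count, mean_long_count = mean_long_count,
    subject_effect_sd = subject_effect_sd, noise_model = noise_model,
    seed = as.integer(seed)
  ), class = "safconn_cohort_spec")
}

# chain-adjacency region system used by the ensemble generator
chain_regions <- function(n_per_hemi) {
  n <- n_per_hemi
  regions <- data.frame(
    id = 1:(2L * n),
    name = rep(paste0("wedge_", seq_len(n)), 2L),
    hemisphere = rep(c("L", "R"), each = n),
    stringsAsFactors = FALSE
  )
  A <- matrix(0L, 2L * n, 2L * n, dimnames = list(regions$id, regions$id))
  for (w in seq_len(n - 1L)) {
    A[w, w + 1L] <- A[w + 1L, w] <- 1L
    A[n + w, n + w + 1L] <- A[n + w + 1L, n + w] <- 1L
  }
  # pair lists (upper triangle, same hemisphere)
  same <- outer(regions$hemisphere, regions$hemisphere, "==")
  up <- upper.tri(A)
  adj_idx <- which(up & A == 1L, arr.ind = TRUE)
  long_idx <- which(up & same & A == 0L, arr.ind = TRUE)
  list(regions = regions,
       adjacency = structure(A, class = c("safconn_adjacency", class(A))),
       adjacent_pairs = adj_idx, long_pairs = long_idx)
}

#' Generate a paired multi-resolution connectome ensemble
#'
#' For subject s with multiplier `m_s = exp(eps_s)`,
#' `eps_s ~ N(0, subject_effect_sd^2)` shared across conditions (paired
#' design): each adjacent-pair entry at condition r is drawn
#' `Poisson(attenuation[r] * mean_short_count * m_s)` and each non-adjacent
#' same-hemisphere pair `Poisson(mean_long_count * m_s)` (their means with
#' `noise_model = "none"`). Matrices are symmetric with zero diagonal and
#' zero cross-hemisphere entries.
#'
#' The analytic ground truth is returned alongside: with total reference
#' short/long strengths `S0 = n_adjacent_pairs * mean_short_count` and
#' `L0 = n_long_pairs * mean_long_count`, the expected GSCF at condition r
#' is `a_r S0 / (a_r S0 + L0)`.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `safconn_ensemble`: `connectomes` (nested list
#'   `[[subject]][[condition]]` of matrices), `subjects`, `regions`,
#'   `adjacency`, `ground_truth` (expected GSCF per condition, expected
#'   relative differences vs reference, per-pair means) and `spec`.
#' @export
make_connectome_ensemble <- function(spec) {
  stopifnot(inherits(spec, "safconn_cohort_spec"))
  sys <- chain_regions(spec$n_regions_per_hemisphere)
  n_adj <- nrow(sys$adjacent_pairs)
  n_long <- nrow(sys$long_pairs)
  S0 <- n_adj * spec$mean_short_count
  L0 <- n_long * spec$mean_long_count
  a <- spec$attenuation
  expected_gscf <- a * S0 / (a * S0 + L0)
  ref_gscf <- expected_gscf[[1]]
  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  nreg <- nrow(sys$regions)

  subj_seeds <- derive_seeds(spec$seed, spec$n_subjects)
  connectomes <- vector("list", spec$n_subjects)
  names(connectomes) <- subjects
  for (s in seq_len(spec$n_subjects)) {
    per_cond <- with_seed(subj_seeds[s], {
      eps <- stats::rnorm(1, 0, spec$subject_effect_sd)
      m_s <- exp(eps)
      cond_seeds <- sample.int(.Machine$integer.max - 1L, length(spec$resolutions))
      out <- vector("list", length(spec$resolutions))
      names(out) <- spec$resolutions
      for (r in seq_along(spec$resolutions)) {
        mu_short <- a[[r]] * spec$mean_short_count * m_s
        mu_long <- spec$mean_long_count * m_s
        counts <- with_seed(cond_seeds[r], {
          if (spec$noise_model == "poisson") {
            c(stats::rpois(n_adj, mu_short), stats::rpois(n_long, mu_long))
          } else {
            c(rep(mu_short, n_adj), rep(mu_long, n_long))
          }
        })
        W <- matrix(0, nreg, nreg,
                    dimnames = list(sys$regions$id, sys$regions$id))
        idx <- rbind(sys$adjacent_pairs, sys$long_pairs)
        W[idx] <- counts
        W[idx[, 2:1, drop = FALSE]] <- counts
        out[[r]] <- W
      }
      out
    })
    connectomes[[s]] <- per_cond
  }
  structure(list(
    connectomes = connectomes, subjects = subjects,
    regions = sys$regions, adjacency = sys$adjacency,
    ground_truth = list(
      expected_gscf = expected_gscf,
      expected_relative_difference_pct =
        100 * (expected_gscf - ref_gscf) / ref_gscf,
      S0 = S0, L0 = L0,
      n_adjacent_pairs = n_adj, n_long_pairs = n_long
    ),
    spec = spec
  ), class = "safconn_ensemble")
}

#' GSCF table for an ensemble
#'
#' Computes GSCF for every subject and condition of a synthetic ensemble.
#'
#' @param ens a [make_connectome_ensemble()] result.
#' @return data.frame with columns `subject`, `condition`, `gscf`.
#' @export
ensemble_gscf_table <- function(ens) {
  stopifnot(inherits(ens, "safconn_ensemble"))
  rows <- list()
  for (s in ens$subjects) {
    for (r in names(ens$connectomes[[s]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, condition = r,
        gscf = gscf(ens$connectomes[[s]][[r]], ens$adjacency),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-region RSCF matrix for one ensemble condition
#'
#' @param ens a [make_connectome_ensemble()] result.
#' @param condition condition label.
#' @return region x subject matrix of RSCF values.
#' @export
ensemble_rscf_matrix <- function(ens, condition) {
  stopifnot(inherits(ens, "safconn_ensemble"))
  if (!condition %in% ens$spec$resolutions) {
    stop("unknown condition: ", condition)
  }
  sapply(ens$subjects, function(s) {
    rscf(ens$connectomes[[s]][[condition]], ens$adjacency)
  })
}

#' Write / read an ensemble as TSV matrices plus a JSON manifest
#'
#' One TSV connectivity matrix per subject/condition
#' (`<subject>_<condition>.tsv`), the adjacency and region table, and a
#' `manifest.json` carrying the cohort spec and analytic ground truth.
#'
#' @param ens a [make_connectome_ensemble()] result.
#' @param dir output directory (created if needed).
#' @return the directory (write) or a `safconn_ensemble` (read).
#' @export
write_ensemble <- function(ens, dir) {
  stopifnot(inherits(ens, "safconn_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in ens$subjects) {
    for (r in names(ens$connectomes[[s]])) {
      write_matrix_tsv(ens$connectomes[[s]][[r]],
                       file.path(dir, paste0(s, "_", r, ".tsv")))
    }
  }
  write_adjacency_tsv(ens$adjacency, file.path(dir, "adjacency.tsv"))
  utils::write.table(ens$regions, file.path(dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  spec_out <- unclass(ens$spec)
  spec_out$attenuation <- as.list(spec_out$attenuation) # keep names in JSON
  manifest <- list(
    subjects = ens$subjects, resolutions = ens$spec$resolutions,
    spec = spec_out, ground_truth = ens$ground_truth
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  regions <- utils::read.delim(file.path(dir, "regions.tsv"),
                               stringsAsFactors = FALSE)
  A <- read_adjacency_tsv(file.path(dir, "adjacency.tsv"))
  sp <- manifest$spec
  spec <- cohort_spec(sp$n_subjects, sp$n_regions_per_hemisphere,
                      sp$resolutions, unlist(sp$attenuation),
                      sp$mean_short_count, sp$mean_long_count,
                      sp$subject_effect_sd, sp$noise_model, sp$seed)
  connectomes <- lapply(manifest$subjects, function(s) {
    out <- lapply(manifest$resolutions, function(r) {
      read_matrix_tsv(file.path(dir, paste0(s, "_", r, ".tsv")))
    })
    names(out) <- manifest$resolutions
    out
  })
  names(connectomes) <- manifest$subjects
  gt <- manifest$ground_truth
  gt$expected_gscf <- unlist(gt$expected_gscf)
  gt$expected_relative_difference_pct <-
    unlist(gt$expected_relative_difference_pct)
  structure(list(connectomes = connectomes, subjects = manifest$subjects,
                 regions = regions, adjacency = A, ground_truth = gt,
                 spec = spec),
            class = "safconn_ensemble")
}
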