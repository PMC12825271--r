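#' Configuration for an end-to-end run
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"from-files"`
#'   (read an ensemble written by [write_ensemble()]).
#' @param seed integer seed; mandatory in simulate mode and applied to the
#'   cohort spec so one seed reproduces the whole run.
#' @param cohort a [cohort_spec()] (simulate mode; default spec if NULL).
#' @param input_dir ensemble directory (from-files mode).
#' @param fdr_level,sw_alpha,zero_policy statistical options, see
#'   [compare_gscf()].
#' @param atlas_breaks histogram bin edges for the group RSCF atlas.
#' @return validated list of class `safconn_run_config`.
#' @export
run_config <- function(mode = c("simulate", "from-files"), seed = NULL,
                       cohort = NULL, input_dir = NULL, fdr_level = 0.05,
                       sw_alpha = 0.05, zero_policy = "drop",
                       atlas_breaks = seq(0, 1, by = 0.05)) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (is.null(seed)) stop("simulate mode requires a seed")
    if (is.null(cohort)) cohort <- cohort_spec(seed = as.integer(seed))
    stopifnot(inherits(cohort, "safconn_cohort_spec"))
    cohort$seed <- as.integer(seed)
  } else {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stop("from-files mode requires an existing input_dir")
    }
  }
  structure(list(mode = mode, seed = seed, cohort = cohort,
                 input_dir = input_dir, fdr_level = fdr_level,
                 sw_alpha = sw_alpha, zero_policy = zero_policy,
                 atlas_breaks = atlas_breaks),
            class = "safconn_run_config")
}

#' Run the full analysis: ensemble, SCF metrics, statistics, atlas
#'
#' Executes simulate (or load) -> per-subject GSCF/RSCF -> paired
#' cross-resolution GSCF comparisons -> per-region RSCF comparisons
#' (lowest vs highest resolution) -> Top-10 reduction table -> group RSCF
#' atlas at the reference resolution, writing every table as TSV under
#' `out_dir/tables/` plus a JSON provenance manifest. Deterministic: the
#' same config and seed reproduce every table byte-identically.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return list of class `safconn_results` with all tables in memory and
#'   `paths` to the written files.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "safconn_run_config"))
  stage <- "setup"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  tab <- function(name) file.path(out_dir, "tables", name)

  ens <- run_stage("ensemble", {
    if (config$mode == "simulate") {
      e <- make_connectome_ensemble(config$cohort)
      write_ensemble(e, file.path(out_dir, "connectomes"))
      e
    } else {
      read_ensemble(config$input_dir)
    }
  })
  conditions <- ens$spec$resolutions
  ref <- conditions[1]
  low <- conditions[length(conditions)]

  gscf_tab <- run_stage("gscf", ensemble_gscf_table(ens))
  write_tsv_plain(gscf_tab, tab("gscf.tsv"))

  gscf_cmp <- run_stage("compare_gscf", {
    compare_gscf(gscf_tab, conditions, config$fdr_level, config$sw_alpha,
                 config$zero_policy)
  })
  write_tsv_plain(gscf_cmp, tab("gscf_comparisons.tsv"))

  rscf_by_cond <- run_stage("rscf", {
    out <- lapply(conditions, function(r) ensemble_rscf_matrix(ens, r))
    names(out) <- conditions
    out
  })
  for (r in conditions) {
    write_matrix_tsv(rscf_by_cond[[r]], tab(paste0("rscf_", r, ".tsv")))
  }

  rscf_cmp <- run_stage("compare_rscf", {
    compare_rscf(rscf_by_cond[[low]], rscf_by_cond[[ref]], config$fdr_level,
                 config$sw_alpha, config$zero_policy)
  })
  write_tsv_plain(rscf_cmp$comparisons, tab("rscf_comparisons.tsv"))

  top10 <- run_stage("top10", {
    diffs <- matrix(rscf_cmp$comparisons$mean_relative_difference_pct,
                    ncol = 1,
                    dimnames = list(rscf_cmp$comparisons$region, "method"))
    reg <- ens$regions[match(rscf_cmp$comparisons$region, ens$regions$id), ]
    top10_frequency(diffs, reg)
  })
  write_tsv_plain(top10$frequency, tab("top10.tsv"))

  atlas <- run_stage("atlas", {
    per_subject <- lapply(seq_len(ncol(rscf_by_cond[[ref]])), function(s) {
      rscf_by_cond[[ref]][, s]
    })
    group_rscf_atlas(per_subject, config$atlas_breaks)
  })
  write_tsv_plain(atlas$atlas, tab("atlas.tsv"))
  write_tsv_plain(atlas$histogram, tab("atlas_histogram.tsv"))

  manifest <- run_stage("manifest", list(
    package_version = as.character(utils::packageVersion("safconn")),
    mode = config$mode, seed = config$seed,
    cohort_spec = if (!is.null(config$cohort)) unclass(config$cohort),
    conditions = conditions,
    statistics = list(fdr_level = config$fdr_level,
                      sw_alpha = config$sw_alpha,
                      zero_policy = config$zero_policy),
    counts = list(
      n_subjects = length(ens$subjects),
      n_regions = nrow(ens$regions),
      n_gscf_comparisons = nrow(gscf_cmp),
      n_rscf_regions_tested = nrow(rscf_cmp$comparisons),
      n_rscf_regions_excluded = length(rscf_cmp$excluded_regions),
      n_undefined_region_values =
        sum(vapply(rscf_by_cond, function(m) sum(is.na(m)), numeric(1)))
    ),
    tables = list.files(file.path(out_dir, "tables"))
  ))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(ensemble = ens, gscf = gscf_tab, gscf_comparisons = gscf_cmp,
                 rscf = rscf_by_cond, rscf_comparisons = rscf_cmp,
                 top10 = top10, atlas = atlas, manifest = manifest,
                 paths = list(out_dir = out_dir,
                              tables = file.path(out_dir, "tables"))),
            class = "safconn_results")
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sweep SAF-definition variants over a tractogram
#'
#' Recomputes the connectome and SCF metrics under alternative short-range
#' definitions — including intra-regional connections and/or imposing a
#' streamline length threshold — and reports, per variant, the GSCF of each
#' condition and the sign of every cross-condition GSCF difference, plus
#' whether those signs agree across all variants.
#'
#' @param tractograms a named list of [tractogram()] objects (one per
#'   condition, reference first), or a single tractogram.
#' @param parc the [parcellation()] shared by all conditions.
#' @param A adjacency matrix.
#' @param variants list of lists with `include_intra` and
#'   `length_threshold_mm` (NULL = no threshold); the first variant is the
#'   baseline.
#' @param search_radius_mm endpoint search radius (see [assign_endpoints()]).
#' @return list with `gscf` (variant x condition data.frame), `rscf`
#'   (list of variant -> region x condition matrix), `sign_consistent`
#'   (logical, TRUE when every cross-condition difference keeps the same
#'   sign in all variants).
#' @export
variant_sweep <- function(tractograms, parc, A,
                          variants = list(
                            list(include_intra = FALSE, length_threshold_mm = NULL),
                            list(include_intra = TRUE, length_threshold_mm = NULL),
                            list(include_intra = FALSE, length_threshold_mm = 50),
                            list(include_intra = TRUE, length_threshold_mm = 50)
                          ),
                          search_radius_mm = 2) {
  if (inherits(tractograms, "safconn_tractogram")) {
    tractograms <- list(condition = tractograms)
  }
  conds <- names(tractograms)
  vlab <- vapply(variants, function(v) {
    paste0("intra=", isTRUE(v$include_intra), ",thr=",
           if (is.null(v$length_threshold_mm)) "none" else v$length_threshold_mm)
  }, character(1))
  g <- matrix(NA_real_, length(variants), length(conds),
              dimnames = list(vlab, conds))
  rmats <- vector("list", length(variants))
  names(rmats) <- vlab
  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    rm_ <- NULL
    for (ci in seq_along(conds)) {
      W <- connectome_from_tractogram(
        tractograms[[ci]], parc, search_radius_mm,
        include_intra = isTRUE(v$include_intra),
        length_threshold_mm = v$length_threshold_mm
      )
      g[vi, ci] <- gscf(W, A)
      rv <- rscf(W, A)
      rm_ <- cbind(rm_, rv)
    }
    colnames(rm_) <- conds
    rmats[[vi]] <- rm_
  }
  sign_consistent <- TRUE
  if (length(conds) >= 2L) {
    prs <- utils::combn(length(conds), 2L)
    for (k in seq_len(ncol(prs))) {
      s <- sign(g[, prs[2, k]] - g[, prs[1, k]])
      if (length(unique(s[!is.na(s)])) > 1L) sign_consistent <- FALSE
    }
  }
  list(gscf = as.data.frame(g), rscf = rmats, sign_consistent = sign_consistent)
}
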