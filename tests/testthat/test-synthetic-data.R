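test_that("ribbon parcellations have the declared chain adjacency", {
  rb2 <- make_ribbon_parcellation(2)
  expect_equal(nrow(rb2$parcellation$regions), 4L)
  expect_equal(sum(rb2$adjacency[upper.tri(rb2$adjacency)]), 2L)

  rb5 <- make_ribbon_parcellation(5)
  expect_equal(sum(rb5$adjacency[upper.tri(rb5$adjacency)]), 8L)
  rep5 <- validate_adjacency(rb5$adjacency, rb5$parcellation$regions)
  expect_equal(rep5$n_pairs_L, 4L)
  expect_equal(rep5$n_pairs_R, 4L)
})

test_that("geometric adjacency recovers the analytic chain for many geometries", {
  geoms <- list(
    list(n = 2L, grid = c(40L, 40L, 40L), vox = 1),
    list(n = 3L, grid = c(32L, 32L, 16L), vox = 1.25),
    list(n = 4L, grid = c(48L, 48L, 20L), vox = 0.96),
    list(n = 5L, grid = c(40L, 40L, 40L), vox = 1),
    list(n = 6L, grid = c(56L, 56L, 12L), vox = 1),
    list(n = 8L, grid = c(64L, 64L, 10L), vox = 1)
  )
  for (g in geoms) {
    rb <- make_ribbon_parcellation(g$n, g$grid, g$vox,
                                   inner_radius_mm = 0.3 * g$grid[1] * g$vox,
                                   outer_radius_mm = 0.45 * g$grid[1] * g$vox)
    A <- adjacency_from_labels(rb$parcellation)
    expect_equal(unname(as.matrix(A) * 1), unname(as.matrix(rb$adjacency) * 1),
                 info = paste("n =", g$n))
  }
})

test_that("degenerate ribbon geometry errors name the empty region", {
  # annulus thinner than a voxel on a tiny slab starves some wedges
  expect_error(
    make_ribbon_parcellation(12, c(16L, 16L, 8L), 2,
                             inner_radius_mm = 3, outer_radius_mm = 5),
    "empty region"
  )
  expect_error(make_ribbon_parcellation(1), "at least 2")
  expect_error(
    make_ribbon_parcellation(3, c(10L, 10L, 10L), 1,
                             inner_radius_mm = 12, outer_radius_mm = 18),
    "too small"
  )
})

test_that("synthetic tractograms have the requested composition and are seeded", {
  rb <- fixture_ribbon()
  tg <- fixture_tractogram(rb)
  expect_length(tg$tractogram$streamlines, 100L)
  expect_equal(sum(tg$truth$kind == "short"), 60L)
  expect_equal(sum(tg$truth$kind == "long"), 40L)
  expect_true(all(tg$tractogram$weights == 1))

  tg2 <- fixture_tractogram(rb)
  expect_identical(tg$tractogram$streamlines, tg2$tractogram$streamlines)
  tg3 <- fixture_tractogram(rb, seed = 8L)
  expect_false(identical(tg$tractogram$streamlines, tg3$tractogram$streamlines))

  empty <- make_tractogram(rb, seed = 1)
  expect_length(empty$tractogram$streamlines, 0L)
})

test_that("tractogram pair preconditions are enforced", {
  rb <- fixture_ribbon()
  expect_error(make_tractogram(rb, short_pairs = data.frame(
    region_i = 1, region_j = 6, count = 1
  )), "same-hemisphere")
  expect_error(make_tractogram(rb, short_pairs = data.frame(
    region_i = 1, region_j = 3, count = 1
  )), "not adjacent")
  expect_error(make_tractogram(rb, long_pairs = data.frame(
    region_i = 1, region_j = 2, count = 1
  )), "adjacent")
  expect_error(make_tractogram(rb, short_pairs = data.frame(
    region_i = 1, region_j = 2, count = -1
  )), ">= 0")
})

test_that("U-fibers dip below the ribbon while long fibers run deeper", {
  rb <- fixture_ribbon()
  geom <- attr(rb, "geometry")
  tg <- fixture_tractogram(rb, n_short = 10L, n_long = 10L)
  radial <- function(s) {
    sqrt((s[, 1] - geom$center_mm[1])^2 + (s[, 2] - geom$center_mm[2])^2)
  }
  rmin_short <- sapply(tg$tractogram$streamlines[1:10], function(s) min(radial(s)))
  rmin_long <- sapply(tg$tractogram$streamlines[11:20], function(s) min(radial(s)))
  expect_true(all(rmin_short < geom$inner_radius_mm))      # sub-ribbon arch
  expect_true(all(rmin_long < geom$inner_radius_mm - 5))   # deep route
})

test_that("deterministic ensemble reproduces the analytic GSCF exactly", {
  sp <- cohort_spec(n_subjects = 3, n_regions_per_hemisphere = 5,
                    attenuation = c(hi = 1, lo = 0.8),
                    subject_effect_sd = 0, noise_model = "none", seed = 1)
  ens <- make_connectome_ensemble(sp)
  S0 <- ens$ground_truth$S0
  L0 <- ens$ground_truth$L0
  expect_equal(S0, 8 * 200)   # 4 adjacent pairs per hemisphere
  expect_equal(L0, 12 * 100)  # 6 non-adjacent same-hemisphere pairs each
  for (s in ens$subjects) {
    expect_equal(gscf(ens$connectomes[[s]][["hi"]], ens$adjacency),
                 S0 / (S0 + L0), tolerance = 1e-15)
    expect_equal(gscf(ens$connectomes[[s]][["lo"]], ens$adjacency),
                 0.8 * S0 / (0.8 * S0 + L0), tolerance = 1e-15)
  }
})

test_that("paired structure: log count ratios are subject-independent", {
  sp <- cohort_spec(n_subjects = 6, subject_effect_sd = 0.3,
                    attenuation = c(hi = 1, lo = 0.7),
                    noise_model = "none", seed = 3)
  ens <- make_connectome_ensemble(sp)
  for (s in ens$subjects) {
    hi <- ens$connectomes[[s]][["hi"]]
    lo <- ens$connectomes[[s]][["lo"]]
    adj <- ens$adjacency == 1
    ratios <- log(lo[adj] / hi[adj])
    expect_equal(unname(ratios), rep(log(0.7), sum(adj)), tolerance = 1e-12)
  }
})

test_that("ensemble matrices satisfy the connectome invariants", {
  sp <- cohort_spec(n_subjects = 4, seed = 9)
  ens <- make_connectome_ensemble(sp)
  hemi <- ens$regions$hemisphere
  cross <- outer(hemi, hemi, "!=")
  for (s in ens$subjects) {
    for (r in sp$resolutions) {
      W <- ens$connectomes[[s]][[r]]
      expect_identical(W, t(W))
      expect_true(all(diag(W) == 0))
      expect_true(all(W[cross] == 0))
      expect_true(all(W >= 0))
    }
  }
})

test_that("ensembles are pure functions of their seed", {
  sp <- cohort_spec(n_subjects = 3, seed = 17)
  e1 <- make_connectome_ensemble(sp)
  e2 <- make_connectome_ensemble(sp)
  expect_identical(e1$connectomes, e2$connectomes)
  e3 <- make_connectome_ensemble(cohort_spec(n_subjects = 3, seed = 18))
  expect_false(identical(e1$connectomes, e3$connectomes))
})

test_that("cohort specs validate their condition labels and parameters", {
  expect_error(cohort_spec(attenuation = c(hi = 1, low = 0.8)), "missing|unknown")
  expect_error(cohort_spec(attenuation = c(hi = 0.9, lo = 0.8)), "reference")
  expect_error(cohort_spec(attenuation = c(hi = 1, lo = 1.2)), "\\(0, 1\\]")
  expect_error(cohort_spec(mean_short_count = 0), "mean_short_count")
  expect_error(cohort_spec(subject_effect_sd = -1), "subject_effect_sd")
})

test_that("b=0 series respect their noise model and seed", {
  b0 <- make_b0_series(c(12, 12, 12), 5, 100, 0, seed = 1)
  flat <- matrix(b0$series$data, ncol = 5)
  sds <- apply(flat[b0$mask, ], 1, sd)
  expect_true(all(sds == 0))
  expect_true(all(flat[!b0$mask, ] == 0))

  a <- make_b0_series(c(12, 12, 12), 5, 100, 10, seed = 4)
  b <- make_b0_series(c(12, 12, 12), 5, 100, 10, seed = 4)
  expect_identical(a$series$data, b$series$data)
  expect_error(make_b0_series(c(8, 8, 8), 1, 100, 1), "n_volumes")
})
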