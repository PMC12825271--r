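test_that("streamline lengths match analytic geometry", {
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(streamline_length(rbind(c(1, 2, 3))), 0)
  theta <- seq(0, pi, length.out = 10001)
  semi <- cbind(10 * cos(theta), 10 * sin(theta), 0)
  expect_equal(streamline_length(semi), 10 * pi, tolerance = 1e-3 / (10 * pi))
})

test_that("endpoints map to their containing voxel with a bounded fallback", {
  lab <- array(0L, c(10L, 10L, 10L))
  lab[2, 2, 2] <- 1L
  parc <- parcellation(lab, data.frame(id = 1L, name = "a", hemisphere = "L"))
  # voxel (1,1,1) in 0-based indices has center (1,1,1) mm
  inside <- tractogram(list(rbind(c(1.2, 0.9, 1.1), c(1, 1, 1))))
  a1 <- assign_endpoints(inside, parc)
  expect_equal(a1$region_i, 1L)
  expect_equal(a1$region_j, 1L)
  # 3 mm away from the only label with a 2 mm radius: unassigned
  far <- tractogram(list(rbind(c(1, 1, 4.2), c(1, 1, 1))))
  a2 <- assign_endpoints(far, parc, search_radius_mm = 2)
  expect_true(is.na(a2$region_i))
  expect_equal(a2$region_j, 1L)
  # within the radius the nearest labelled voxel wins
  nearby <- tractogram(list(rbind(c(1, 1, 2.6), c(1, 1, 1))))
  a3 <- assign_endpoints(nearby, parc, search_radius_mm = 2)
  expect_equal(a3$region_i, 1L)
  # equidistant candidates break ties to the lowest region id
  lab2 <- array(0L, c(5L, 5L, 5L))
  lab2[1, 2, 2] <- 7L
  lab2[3, 2, 2] <- 4L
  parc2 <- parcellation(lab2, data.frame(id = c(4L, 7L), name = c("a", "b"),
                                         hemisphere = c("L", "L")))
  mid <- tractogram(list(rbind(c(1, 1, 1), c(1, 1, 1))))
  a4 <- assign_endpoints(mid, parc2, search_radius_mm = 2)
  expect_equal(a4$region_i, 4L)
})

test_that("synthetic tractogram endpoints are recovered perfectly", {
  rb <- fixture_ribbon()
  tg <- fixture_tractogram(rb)
  asn <- assign_endpoints(tg$tractogram, rb$parcellation)
  expect_equal(asn$region_i, tg$truth$region_i)
  expect_equal(asn$region_j, tg$truth$region_j)
})

mini_regions <- data.frame(id = 1:4, name = c("a", "b", "a", "b"),
                           hemisphere = c("L", "L", "R", "R"))

test_that("connectivity accumulation follows the association-fiber rules", {
  asn <- data.frame(region_i = c(1L, 2L, 1L, 1L, 1L, NA),
                    region_j = c(2L, 1L, 3L, 1L, 2L, 2L))
  lens <- rep(10, 6)
  wts <- rep(1, 6)
  W <- build_connectivity(asn, lens, wts, mini_regions)
  # three L1-L2 streamlines (two orientations), one cross-hemisphere, one
  # intra-regional, one unassigned
  expect_equal(W$w[1, 2], 3)
  expect_equal(W$w[2, 1], 3)
  expect_equal(sum(W$w), 6)               # symmetric double entry only
  expect_equal(W$w[1, 3], 0)              # commissural-like excluded
  expect_equal(W$report$n_commissural_like, 1L)
  expect_equal(W$report$n_unassigned, 1L)
  expect_equal(W$report$n_intra_dropped, 1L)

  Wi <- build_connectivity(asn, lens, wts, mini_regions, include_intra = TRUE)
  expect_equal(Wi$w[1, 1], 1)             # diagonal filled once, not doubled
  expect_equal(sum(diag(Wi$w)), 1)
})

test_that("strength conservation and order invariance hold", {
  rb <- fixture_ribbon()
  tg <- fixture_tractogram(rb)
  W <- connectome_from_tractogram(tg$tractogram, rb$parcellation)
  expect_equal(sum(W$w) - sum(diag(W$w)), 2 * 100)
  expect_identical(W$w, t(W$w))

  set.seed(3)
  perm <- sample(100)
  tg_perm <- tractogram(tg$tractogram$streamlines[perm],
                        tg$tractogram$weights[perm])
  W2 <- connectome_from_tractogram(tg_perm, rb$parcellation)
  expect_equal(W2$w, W$w)
})

test_that("length thresholding restricts the SAF numerator as configured", {
  asn <- data.frame(region_i = c(1L, 1L, 1L), region_j = c(2L, 2L, 2L))
  lens <- c(10, 60, 40)
  wts <- c(1, 1, 1)
  W <- build_connectivity(asn, lens, wts, mini_regions,
                          length_threshold_mm = 50)
  expect_equal(W$w[1, 2], 3)              # denominator keeps all
  expect_equal(W$saf_numerator[1, 2], 2)  # only <= 50 mm count as short-range
  expect_true(all(W$saf_numerator <= W$w))

  Wb <- build_connectivity(asn, lens, wts, mini_regions,
                           length_threshold_mm = 50, threshold_scope = "both")
  expect_equal(Wb$w[1, 2], 2)
  expect_equal(Wb$report$n_long_excluded, 1L)

  Winf <- build_connectivity(asn, lens, wts, mini_regions,
                             length_threshold_mm = Inf)
  expect_equal(Winf$saf_numerator, Winf$w)
})

test_that("misaligned or unknown inputs are rejected", {
  asn <- data.frame(region_i = 1L, region_j = 2L)
  expect_error(build_connectivity(asn, numeric(0), 1, mini_regions), "aligned")
  expect_error(
    build_connectivity(data.frame(region_i = 9L, region_j = 2L), 1, 1,
                       mini_regions),
    "absent"
  )
  expect_error(tractogram(list(rbind(c(0, 0, 0))), weights = c(1, 2)), "length")
  expect_error(tractogram(list(rbind(c(0, 0, 0))), weights = -1), "positive")
})

test_that("TCK files round trip at float32 precision", {
  rb <- fixture_ribbon()
  tg <- fixture_tractogram(rb)$tractogram
  tg$weights <- runif(100, 0.5, 2)
  f <- tempfile(fileext = ".tck")
  wf <- tempfile(fileext = ".txt")
  write_tractogram_tck(tg, f, weights_path = wf)
  back <- read_tractogram_tck(f, weights_path = wf)
  expect_length(back$streamlines, 100L)
  expect_equal(vapply(back$streamlines, nrow, integer(1)),
               vapply(tg$streamlines, nrow, integer(1)))
  maxerr <- max(mapply(function(a, b) max(abs(a - b)),
                       back$streamlines, tg$streamlines))
  expect_lt(maxerr, 1e-4)  # float32 rounding of ~40 mm coordinates
  expect_equal(back$weights, tg$weights, tolerance = 1e-12)
})

test_that("TCK edge cases behave: empty files, bad weights, bad magic", {
  f <- tempfile(fileext = ".tck")
  write_tractogram_tck(tractogram(), f)
  expect_length(read_tractogram_tck(f)$streamlines, 0L)

  tg <- tractogram(list(rbind(c(0, 0, 0), c(1, 1, 1))))
  write_tractogram_tck(tg, f)
  wf <- tempfile()
  writeLines(c("1.0", "2.0"), wf)
  expect_error(read_tractogram_tck(f, weights_path = wf), "weights file")

  bad <- tempfile(fileext = ".tck")
  writeLines("not a track file", bad)
  expect_error(read_tractogram_tck(bad), "magic|header")
})
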