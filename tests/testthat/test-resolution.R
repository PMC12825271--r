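test_that("k-space truncation preserves constants and the image mean", {
  v <- volume(array(3.7, c(16, 12, 10)))
  for (target in list(c(8, 6, 5), c(16, 12, 10), c(3, 3, 3))) {
    d <- downsample_kspace(v, target)
    expect_equal(max(abs(d$data - 3.7)), 0, tolerance = 1e-12)
  }
  set.seed(2)
  x <- volume(array(rnorm(16 * 12 * 10, mean = 5), c(16, 12, 10)))
  d <- downsample_kspace(x, c(7, 6, 4), taper_fraction = 0.3)
  expect_equal(mean(d$data), mean(x$data), tolerance = 1e-12)
})

test_that("in-band cosines survive truncation exactly, out-of-band ones vanish", {
  src <- c(32L, 32L, 32L)
  tgt <- c(16L, 16L, 16L)
  # |k| = 2 is inside the unit-gain band of the 16-point window at taper 0.2
  ph_in <- make_phantom_volume(src, components = list(
    list(freq = c(2, 0, 0), amplitude = 2, phase = 0.4)
  ))
  ref <- make_phantom_volume(tgt, components = list(
    list(freq = c(2, 0, 0), amplitude = 2, phase = 0.4)
  ))
  d <- downsample_kspace(ph_in, tgt, taper_fraction = 0.2)
  expect_lt(max(abs(d$data - ref$data)), 1e-10)
  expect_equal(d$voxel_size_mm, c(2, 2, 2))

  # |k| = 12 lies outside the retained 16-point window: only DC remains
  ph_out <- make_phantom_volume(src, components = list(
    list(freq = c(12, 0, 0), amplitude = 2)
  ), dc_level = 1)
  d2 <- downsample_kspace(ph_out, tgt)
  expect_lt(max(abs(d2$data - 1)), 1e-10 * 2)
})

test_that("truncation with target = source and taper 0 is the identity", {
  set.seed(5)
  x <- volume(array(rnorm(9 * 8 * 7), c(9, 8, 7)))
  d <- downsample_kspace(x, c(9, 8, 7), taper_fraction = 0)
  expect_equal(max(abs(d$data - x$data)), 0, tolerance = 1e-12)
})

test_that("truncation never increases energy about the mean (Parseval)", {
  set.seed(11)
  for (rep in 1:25) {
    s <- sample(6:14, 3, replace = TRUE)
    m <- pmin(s, sample(3:14, 3, replace = TRUE))
    x <- volume(array(rnorm(prod(s)), s))
    d <- downsample_kspace(x, m, taper_fraction = runif(1, 0, 0.6))
    e0 <- sum((x$data - mean(x$data))^2)
    e1 <- sum((d$data - mean(d$data))^2)
    expect_lte(e1, e0 * (1 + 1e-12))
  }
})

test_that("invalid truncation targets are rejected", {
  v <- volume(array(0, c(8, 8, 8)))
  expect_error(downsample_kspace(v, c(9, 8, 8)), "exceeds source")
  expect_error(downsample_kspace(v, c(0, 4, 4)), "positive")
  expect_error(downsample_kspace(v, c(4, 4, 4), taper_fraction = 1.5), "taper")
})

test_that("4D volumes are truncated volume-wise", {
  arr <- array(0, c(8, 8, 8, 3))
  for (v in 1:3) arr[, , , v] <- v
  d <- downsample_kspace(volume(arr), c(4, 4, 4))
  for (v in 1:3) expect_equal(max(abs(d$data[, , , v] - v)), 0, tolerance = 1e-12)
})

test_that("spline up-sampling reproduces constants at every order", {
  v <- volume(array(2.5, c(9, 7, 8)), voxel_size_mm = c(2, 2, 2))
  for (o in 0:5) {
    u <- upsample_spline(v, c(19, 14, 16), spline_order = o)
    expect_equal(max(abs(u$data - 2.5)), 0, tolerance = 1e-12)
  }
  expect_equal(u$voxel_size_mm, c(2, 2, 2) * c(9, 7, 8) / c(19, 14, 16))
})

test_that("cubic splines reproduce a linear ramp in the interior", {
  N <- 48L
  ramp <- volume(array(rep(0:(N - 1), 64), c(N, 8L, 8L)))
  u <- upsample_spline(ramp, c(2L * N, 16L, 16L))
  expected <- (0:(2 * N - 1)) * N / (2 * N)
  interior <- 41:56 # >= 20 source samples from either boundary
  err <- max(abs(sweep(u$data, 1, expected)[interior, 8, 8]))
  expect_lt(err, 1e-9)
})

test_that("down-then-up round trip recovers an in-band phantom within 1%", {
  src <- c(32L, 32L, 32L)
  ph <- make_phantom_volume(src, components = list(
    list(freq = c(1, 2, 0), amplitude = 1, phase = 0.3),
    list(freq = c(0, 0, 2), amplitude = 0.5)
  ), dc_level = 3)
  down <- downsample_kspace(ph, c(16, 16, 16), taper_fraction = 0.2)
  up <- upsample_spline(down, src, boundary = "periodic")
  expect_lt(max(abs(up$data - ph$data)), 0.01 * diff(range(ph$data)))
})

test_that("up-sampling validates its arguments", {
  v <- volume(array(0, c(8, 8, 8)))
  expect_error(upsample_spline(v, c(4, 8, 8)), "at least as fine")
  expect_error(upsample_spline(v, c(16, 16, 16), spline_order = 6), "spline_order")
  expect_error(upsample_spline(v, c(16, 16, 16), spline_order = -1), "spline_order")
  expect_error(upsample_spline(v), "exactly one")
  expect_error(upsample_spline(v, target_shape = c(16, 16, 16),
                               target_voxel_size_mm = 0.5), "exactly one")
  # voxel-size interface: 8 voxels at 2 mm -> 16 at 1 mm
  u <- upsample_spline(volume(array(1, c(8, 8, 8)), voxel_size_mm = c(2, 2, 2)),
                       target_voxel_size_mm = 1)
  expect_equal(dim(u$data), c(16L, 16L, 16L))
})

test_that("phantom volumes have exactly the declared Fourier support", {
  ph <- make_phantom_volume(c(16, 16, 16), components = list(
    list(freq = c(3, 0, 0), amplitude = 1.5, phase = 0.7),
    list(freq = c(0, 2, 5), amplitude = 0.5)
  ), dc_level = 2)
  F <- fft(ph$data) / prod(dim(ph$data))
  allowed <- rbind(c(0, 0, 0), c(3, 0, 0), c(-3, 0, 0),
                   c(0, 2, 5), c(0, -2, -5))
  allowed_idx <- (allowed %% 16) + 1
  mask <- array(TRUE, dim(F))
  for (r in seq_len(nrow(allowed_idx))) {
    mask[allowed_idx[r, 1], allowed_idx[r, 2], allowed_idx[r, 3]] <- FALSE
  }
  expect_lt(max(abs(F[mask])), 1e-10)
  # amplitude-2 cosine spans max - min = 4 up to grid sampling of extrema
  ph2 <- make_phantom_volume(c(64, 8, 8), components = list(
    list(freq = c(1, 0, 0), amplitude = 2)
  ))
  expect_equal(diff(range(ph2$data)), 4, tolerance = 1e-2)
  expect_equal(unique(as.vector(make_phantom_volume(c(8, 8, 8), dc_level = 5)$data)), 5)
  expect_error(make_phantom_volume(c(8, 8, 8), components = list(
    list(freq = c(5, 0, 0), amplitude = 1)
  )), "representable")
})

test_that("tSNR matches its two-point closed form and error contracts", {
  arr <- array(0, c(1, 1, 1, 2))
  arr[1, 1, 1, ] <- c(9, 11)
  mask <- array(TRUE, c(1, 1, 1))
  r <- tsnr(arr, mask)
  expect_equal(r$scalar, 10 / sqrt(2))
  expect_equal(r$map[1, 1, 1], 10 / sqrt(2))

  same <- array(7, c(2, 2, 2, 2))
  expect_error(tsnr(same, array(TRUE, c(2, 2, 2))), "zero")
  expect_error(tsnr(arr, array(FALSE, c(1, 1, 1))), "empty")
  expect_error(tsnr(array(0, c(2, 2, 2, 1)), array(TRUE, c(2, 2, 2))), "2 volumes")
})

test_that("tSNR recovers the simulated mean/sd ratio", {
  b0 <- make_b0_series(c(36, 36, 36), n_volumes = 100, mean_signal = 100,
                       noise_sd = 10, seed = 42)
  expect_gte(sum(b0$mask), 1e4)
  r <- tsnr(b0$series, b0$mask)
  expect_gte(r$scalar, 9.5)
  expect_lte(r$scalar, 10.5)
})

test_that("masked mean agrees with a brute-force voxel loop", {
  expect_equal(masked_mean(array(0.37, c(3, 3, 3)), array(TRUE, c(3, 3, 3))), 0.37)
  m2 <- array(FALSE, c(2, 1, 1)); m2[] <- TRUE
  expect_equal(masked_mean(array(c(0.2, 0.4), c(2, 1, 1)), m2), 0.3)
  set.seed(9)
  for (rep in 1:5) {
    map <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
    mask <- array(runif(4 * 5 * 6) > 0.5, c(4, 5, 6))
    if (!any(mask)) mask[1] <- TRUE
    acc <- 0; nn <- 0
    for (i in 1:4) for (j in 1:5) for (k in 1:6) {
      if (mask[i, j, k]) { acc <- acc + map[i, j, k]; nn <- nn + 1 }
    }
    expect_equal(masked_mean(map, mask), acc / nn, tolerance = 1e-12)
  }
  expect_error(masked_mean(array(1, c(2, 2, 2)), array(FALSE, c(2, 2, 2))), "empty")
})

test_that("NIfTI round trip preserves data and geometry", {
  v <- volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
              voxel_size_mm = c(0.96, 1.25, 2), origin_mm = c(-10, 3, 0.5))
  f <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(v, f)
  r <- read_volume_nifti(f)
  expect_equal(r$data, v$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(r$voxel_size_mm, v$voxel_size_mm, tolerance = 1e-5)
  expect_equal(r$origin_mm, v$origin_mm, tolerance = 1e-5)
})
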