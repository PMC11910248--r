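test_that("spiral directions are unit vectors advancing pole to pole", {
  d <- archimedean_spiral_directions(1000)
  expect_equal(sqrt(rowSums(d^2)), rep(1, 1000), tolerance = 1e-12)
  expect_true(all(diff(d[, "z"]) > 0))
  expect_error(archimedean_spiral_directions(1), "at least 2")
})

test_that("spiral directions are nearly uniform on the sphere", {
  d <- archimedean_spiral_directions(10000)
  expect_lt(sqrt(sum(colMeans(d)^2)), 0.02)
  nn_gc <- function(dd) {
    # nearest-neighbor great-circle distance per point
    g <- dd %*% t(dd)
    diag(g) <- -2
    acos(pmin(apply(g, 1, max), 1))
  }
  d1 <- archimedean_spiral_directions(1000)
  cv <- function(v) sd(v) / mean(v)
  expect_lt(cv(nn_gc(d1)), 0.5)
  # refinement stability: CV changes < 20% from n to 2n
  d2 <- archimedean_spiral_directions(2000)
  expect_lt(abs(cv(nn_gc(d2)) - cv(nn_gc(d1))) / cv(nn_gc(d1)), 0.2)
})

test_that("bSTAR trajectory has paired half-projections on radial lines", {
  tr <- build_bstar_trajectory(n_spokes = 50, samples_per_half = 32,
                               resolution_mm = 0.87)
  expect_equal(tr$n_half, 100L)
  expect_equal(tr$kmax, 1 / (2 * 0.87))
  expect_equal(tr$echo, rep(c(1L, 2L), 50))
  r <- sqrt(rowSums(tr$coords^2))
  expect_equal(max(r), tr$kmax, tolerance = 1e-9)
  # center-out starts at 0, center-in ends at 0 (time order)
  k <- array(t(tr$coords), c(3, tr$n_samp, tr$n_half))
  expect_true(all(abs(k[, 1, tr$echo == 1]) < 1e-12))
  expect_true(all(abs(k[, tr$n_samp, tr$echo == 2]) < 1e-12))
  # collinearity: every half-projection lies on a line through 0
  for (h in c(1, 2, 57)) {
    seg <- tr$coords[(h - 1) * tr$n_samp + seq_len(tr$n_samp), ]
    dir <- seg[which.max(rowSums(seg^2)), ]
    dir <- dir / sqrt(sum(dir^2))
    resid <- seg - outer(as.vector(seg %*% dir), dir)
    expect_lt(max(abs(resid)), 1e-10)
  }
  # radial sample spacing uniform
  rr <- matrix(tr$radius, tr$n_samp)
  expect_equal(max(abs(diff(abs(diff(rr[, 1]))))), 0, tolerance = 1e-12)
  expect_error(build_bstar_trajectory(n_spokes = 0, samples_per_half = 32,
                                      resolution_mm = 1), "geometry")
})

test_that("single-spoke trajectory shares the k = 0 neighborhood", {
  tr <- build_bstar_trajectory(n_spokes = 1, samples_per_half = 16,
                               resolution_mm = 1, ndim = 2)
  expect_equal(tr$n_half, 2L)
  expect_true(any(tr$radius[1:16] == 0) && any(tr$radius[17:32] == 0))
})

test_that("GIRF identity kernel is a no-op and delay shifts the spokes", {
  tr <- build_bstar_trajectory(n_spokes = 6, samples_per_half = 24,
                               resolution_mm = 1)
  ident <- apply_girf(tr, girf_kernel(1))
  expect_equal(ident$coords, tr$coords, tolerance = 1e-12)
  # pure one-sample delay: k positions lag by one gradient integral
  del <- apply_girf(tr, girf_kernel(c(0, 1)))
  k <- matrix(tr$coords[, 1], tr$n_samp)
  kd <- matrix(del$coords[, 1], tr$n_samp)
  expect_equal(kd[2:tr$n_samp, ], k[1:(tr$n_samp - 1), ], tolerance = 1e-12)
  expect_equal(kd[1, ], k[1, ])
  # unit-sum low-pass keeps center-out terminal radius within kmax
  lp <- apply_girf(tr, girf_kernel(c(0.25, 0.5, 0.25), origin = 2))
  expect_equal(nrow(lp$coords), nrow(tr$coords))
  ends <- matrix(lp$radius, tr$n_samp)[tr$n_samp, tr$echo == 1]
  expect_true(all(ends <= tr$kmax + 1e-12))
  expect_error(girf_kernel(numeric(0)), "empty")
})

test_that("radial density weights grow as r^(d-1) with a DC floor", {
  tr <- build_bstar_trajectory(n_spokes = 10, samples_per_half = 32,
                               resolution_mm = 1)
  w <- radial_dcf(tr)
  expect_true(all(w > 0))
  rr <- matrix(tr$radius, tr$n_samp)
  ww <- matrix(w, tr$n_samp)
  for (h in seq_len(ncol(ww))) {
    ord <- order(rr[, h])
    expect_true(all(diff(ww[ord, h]) >= 0))
  }
  # spoke permutation permutes the weights
  perm <- sample(tr$n_half)
  tr_p <- tr
  idx <- as.vector(outer(seq_len(tr$n_samp), (perm - 1) * tr$n_samp, `+`))
  tr_p$coords <- tr$coords[idx, ]
  tr_p$radius <- tr$radius[idx]
  tr_p$echo <- tr$echo[perm]
  expect_equal(radial_dcf(tr_p), w[idx])
})

test_that("density compensation sharpens the point-spread function", {
  tr <- build_bstar_trajectory(n_spokes = 400, samples_per_half = 17,
                               resolution_mm = 6)
  grid <- c(32L, 32L, 32L)
  fov <- 192
  plan <- nufft_plan(tr$coords, grid, fov, width = 4)
  ones <- rep(1 + 0i, nrow(tr$coords))
  psf_d <- Mod(nufft_adjoint(plan, tr$dcf * ones))
  psf_0 <- Mod(nufft_adjoint(plan, ones))
  fwhm <- function(p) {
    prof <- p[, 17, 17] / max(p[, 17, 17])
    sum(prof >= 0.5)
  }
  expect_lt(fwhm(psf_d) / fwhm(psf_0), 1)
})

test_that("acquisition time is spokes times TR", {
  expect_equal(acquisition_time(40000, 4.52), 180.8)
  expect_equal(acquisition_time(0, 4.52), 0)
  expect_equal(acquisition_time(150000, 3.92), 588)
  expect_error(acquisition_time(10, 0), "positive")
})

test_that("undersampling factor follows the documented convention", {
  uhr <- load_protocol("uhr"); hr <- load_protocol("hr_nonmt")
  R_hr <- undersampling_factor(hr)
  expect_equal(attr(R_hr, "convention"), "sphere_nyquist")
  expect_equal(as.numeric(R_hr), pi * (256 / 0.87)^2 / 80000,
               tolerance = 1e-12)
  # more spokes -> smaller R
  hr2 <- hr; hr2$n_spokes <- 2L * hr$n_spokes
  expect_lt(as.numeric(undersampling_factor(hr2)), as.numeric(R_hr))
  # doubling FOV/resolution quadruples R
  hr4 <- hr; hr4$fov_mm <- 2 * hr$fov_mm
  expect_equal(as.numeric(undersampling_factor(hr4)) / as.numeric(R_hr), 4)
  expect_error(undersampling_factor(hr, "voronoi"), "unknown")
})

test_that("trajectory text round-trip preserves geometry and weights", {
  tr <- build_bstar_trajectory(n_spokes = 4, samples_per_half = 12,
                               resolution_mm = 1.5, ndim = 2)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f, kmax = tr$kmax)
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-12)
  expect_equal(tr2$dcf, tr$dcf, tolerance = 1e-12)
  expect_equal(tr2$echo, tr$echo)
  unlink(f)
})
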