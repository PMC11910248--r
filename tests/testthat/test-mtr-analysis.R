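test_that("MTR computation follows 100 (S - S_MT)/S with exclusions", {
  s <- array(2, c(4, 4)); smt <- array(1, c(4, 4))
  m <- compute_mtr(s, smt)
  expect_true(all(m$mtr == 50))
  expect_true(all(compute_mtr(s, s)$mtr == 0))
  # S = 0 voxels are excluded and counted
  s0 <- s; s0[1, 1] <- 0
  expect_message(m0 <- compute_mtr(s0, smt), "excluded")
  expect_equal(m0$n_excluded, 1)
  expect_true(is.na(m0$mtr[1, 1]))
  # out-of-range values are clipped and their fraction recorded
  s2 <- array(1, c(2, 2)); smt2 <- array(c(3, 0.5, 0.5, 0.5), c(2, 2))
  m2 <- compute_mtr(s2, smt2)
  expect_equal(m2$mtr[1, 1], -50)
  expect_equal(m2$frac_out_of_range, 0.25)
  expect_error(compute_mtr(s, array(1, c(2, 2))), "same grid")
})

test_that("MTR round-trips the injected depletion exactly in image space", {
  set.seed(31)
  s <- array(runif(64 * 64, 0.2, 1), c(64, 64))
  mtr_true <- array(runif(64 * 64, 0, 60), c(64, 64))
  smt <- mt_weighted_signal(s, mtr_true)
  m <- compute_mtr(s, smt)
  expect_equal(m$mtr, mtr_true, tolerance = 1e-12)
})

test_that("dual-echo field map inverts the phase evolution", {
  expect_equal(max(abs(fieldmap_from_dual_echo(array(1 + 0i, c(3, 3)),
                                               array(1 + 0i, c(3, 3)), 8))), 0)
  v1 <- array(1 + 0i, c(3, 3))
  v2 <- array(exp(1i * 2.513274), c(3, 3))
  f <- fieldmap_from_dual_echo(v1, v2, 8)
  expect_equal(f[1, 1], 50, tolerance = 1e-4)
  expect_equal(attr(f, "range_hz"), 62.5)
  # 80 Hz at dTE = 8 ms aliases to -45 Hz
  v80 <- array(exp(1i * 2 * pi * 80 * 8e-3), c(3, 3))
  f80 <- fieldmap_from_dual_echo(v1, v80, 8)
  expect_equal(f80[1, 1], -45, tolerance = 1e-9)
  expect_error(fieldmap_from_dual_echo(v1, v2, 0), "positive")
})

test_that("off-resonance coverage counts masked voxels within the bound", {
  f <- array(0, c(8, 8))
  mask <- array(TRUE, c(8, 8))
  expect_equal(offres_coverage(f, mask, 50), 1)
  f[1:2, 1] <- c(60, -70)
  expect_equal(offres_coverage(f, mask, 50), 62 / 64)
  expect_equal(offres_coverage(f, mask, 0), 62 / 64)
  expect_error(offres_coverage(f, array(FALSE, c(8, 8)), 50), "empty")
  # synthetic default field stays almost entirely within +-50 Hz
  fm <- make_offres_map(c(96, 96), 80, 50, seed = 2)
  expect_gte(offres_coverage(fm, array(TRUE, c(96, 96)), 50), 0.99)
})

test_that("histogram peak finds the dominant mode stably across bins", {
  const <- array(40, c(10, 10))
  expect_equal(mtr_histogram_peak(const, mask = array(TRUE, c(10, 10)))$peak_pu,
               40)
  set.seed(32)
  vals <- c(rnorm(4000, 43, 2.5), rnorm(1500, 30, 4))
  arr <- array(vals, c(55, 100))
  mask <- array(TRUE, dim(arr))
  h1 <- mtr_histogram_peak(arr, bin_width = 1, mask = mask)
  expect_lt(abs(h1$peak_pu - 43), 1 + 1e-12)
  # halving the bin width moves the peak by less than one original bin
  h2 <- mtr_histogram_peak(arr, bin_width = 0.5, mask = mask)
  expect_lt(abs(h2$peak_pu - h1$peak_pu), 1)
  # permutation invariance within the mask
  arr_p <- array(sample(vals), dim(arr))
  expect_equal(mtr_histogram_peak(arr_p, bin_width = 1, mask = mask)$peak_pu,
               h1$peak_pu)
  expect_error(mtr_histogram_peak(const, bin_width = 0), "positive")
})

test_that("repeatability summary gives standard sample statistics", {
  r <- repeatability_summary(c(42, 44))
  expect_equal(r$mean, 43)
  expect_equal(r$sd, sqrt(2))
  expect_equal(r$min, 42); expect_equal(r$max, 44)
  expect_equal(repeatability_summary(rep(43.3, 5))$sd, 0)
  expect_error(repeatability_summary(43), "at least 2")
})

test_that("repeatability degrades monotonically with image noise", {
  # image-domain surrogate of the scan-rescan experiment: noisy MT pairs
  set.seed(33)
  s <- array(1, c(48, 48))
  mtr_true <- array(43.3, c(48, 48))
  smt <- mt_weighted_signal(s, mtr_true)
  peak_sd <- vapply(c(0.005, 0.02, 0.06), function(ns) {
    peaks <- vapply(1:8, function(r) {
      n1 <- array(rnorm(48^2, 0, ns), c(48, 48))
      n2 <- array(rnorm(48^2, 0, ns), c(48, 48))
      mtr_histogram_peak(compute_mtr(s + n1, smt + n2))$peak_pu
    }, numeric(1))
    sd(peaks)
  }, numeric(1))
  expect_true(all(diff(peak_sd) >= 0))
})

test_that("apparent SNR is mean-over-sd and scale invariant", {
  img <- array(0, c(20, 20))
  sig <- array(FALSE, c(20, 20)); sig[1:5, 1:5] <- TRUE
  noi <- array(FALSE, c(20, 20)); noi[15:20, 15:20] <- TRUE
  img[sig] <- 100
  set.seed(34)
  img[noi] <- rnorm(36, 0, 5)
  snr <- apparent_snr(img, sig, noi)
  expect_equal(snr, 100 / sd(abs(img[noi])))  # SNR is defined on magnitudes
  expect_equal(apparent_snr(7 * img, sig, noi), snr, tolerance = 1e-12)
  expect_error(apparent_snr(img, sig, sig), "disjoint")
  expect_error(apparent_snr(img, array(FALSE, c(20, 20)), noi), "non-empty")
  flat <- array(1, c(20, 20))
  expect_warning(expect_equal(apparent_snr(flat, sig, noi), Inf), "zero")
})

test_that("doubling simulation noise halves the measured apparent SNR", {
  # a smooth object isolates the noise scaling: no sharp edges, so the
  # noise ROI carries no Gibbs-ringing floor
  n <- 64L; shape <- c(n, n)
  co <- seq(-1, 1, length.out = n)
  r2 <- outer(co^2, co^2, `+`)
  ph <- tiny_phantom(n, voxel = 3, PD = 1)
  ph$PD <- 0.9 * exp(-r2 / (2 * 0.25^2))
  ph$label <- array(ifelse(ph$PD > 0.3, 3L, 0L), shape)
  cm <- coils64()
  proto <- proto2d(R = 1)
  traj <- build_bstar_trajectory(proto, ndim = 2)
  sig_roi <- r2 < 0.05
  noi_roi <- array(FALSE, shape)
  noi_roi[c(1:4, 61:64), ] <- TRUE
  noi_roi <- noi_roi & (r2 > 0.8)
  snr_at <- function(nsd, seed) {
    k <- simulate_bstar(ph, traj, proto, noise_sd = nsd, seed = seed,
                        coil_maps = cm)
    img <- adjoint_recon(k, c(n, n), 192, coil_maps = cm, echo = 1)
    apparent_snr(Mod(img$data), sig_roi, noi_roi)
  }
  s1 <- mean(vapply(1:6, function(r) snr_at(0.5, 400 + r), numeric(1)))
  s2 <- mean(vapply(1:6, function(r) snr_at(1.0, 500 + r), numeric(1)))
  expect_lt(abs(s1 / s2 - 2) / 2, 0.1)
})
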