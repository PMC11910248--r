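wm <- tissue_params(450, 90, 0.7)
aqueous <- tissue_params(150, 100, 1.0)

test_that("tissue and timing constructors validate their invariants", {
  expect_error(tissue_params(-1, 90), "positive")
  expect_error(tissue_params(100, 200), "T2 must not exceed")
  expect_error(tissue_params(450, 90, PD = -0.1), "non-negative")
  expect_error(tissue_params(450, 90, mtr_true = 120), "percent units")
  expect_error(sequence_timing(TR = 4, TE1 = 5), "echo times")
  expect_error(sequence_timing(TR = 4, TE1 = 1, TE2 = 0.5), "echo times")
  expect_error(sequence_timing(TR = 4, TE1 = 1, alpha = 200), "flip angle")
})

test_that("bSSFP signal matches its trivial identities", {
  tm <- sequence_timing(TR = 4.52, TE1 = 0.93, TE2 = 3.51, alpha = 40)
  # alpha -> 0 means no excitation
  tm0 <- tm; tm0$alpha <- 1e-9
  expect_lt(Mod(bssfp_signal(wm, tm0, 0)), 1e-9)
  # magnitude bounded by PD
  f <- seq(-300, 300, by = 5)
  mags <- Mod(bssfp_signal(wm, tm, f))
  expect_true(all(mags <= wm$PD))
  # banding null at 1/(2TR) is the minimum over the period
  null_mag <- Mod(bssfp_signal(wm, tm, banding_frequency(tm$TR)))
  period <- seq(-110.6, 110.6, length.out = 201)
  expect_lte(null_mag, min(Mod(bssfp_signal(wm, tm, period))) + 1e-12)
  expect_error(bssfp_signal(list(T1 = -1, T2 = 90, PD = 1), tm, 0),
               "positive")
})

test_that("frequency response is 1/TR-periodic and even in f", {
  tm <- sequence_timing(TR = 4.52, TE1 = 0.93, TE2 = 3.51, alpha = 40)
  f <- seq(-200, 200, length.out = 81)
  m <- Mod(bssfp_signal(wm, tm, f, TE = 0))
  m_shift <- Mod(bssfp_signal(wm, tm, f + 1 / (tm$TR * 1e-3), TE = 0))
  expect_equal(m, m_shift, tolerance = 1e-10)
  expect_equal(m, rev(m), tolerance = 1e-10)
})

test_that("passband is flat and high relative to the banding null", {
  tm <- sequence_timing(TR = 4.52, TE1 = 0.93, TE2 = 3.51, alpha = 40)
  pass <- Mod(bssfp_signal(wm, tm, seq(-73, 73, by = 1)))
  null_mag <- Mod(bssfp_signal(wm, tm, banding_frequency(tm$TR)))
  expect_gt(min(pass) / null_mag, 2)
})

test_that("banding and passband frequencies follow 1/(2TR) and 1/(3TR)", {
  expect_equal(banding_frequency(4.52), 110.6, tolerance = 1e-3)
  expect_equal(banding_frequency(5), 100)
  expect_equal(banding_frequency(2.86), 174.8, tolerance = 1e-3)
  expect_equal(passband_halfwidth(4.52), 73.7, tolerance = 1e-3)
  expect_equal(passband_halfwidth(3.92), 85.0, tolerance = 0.05)
  for (tr in c(2, 3.92, 4.52, 10))
    expect_equal(passband_halfwidth(tr) / banding_frequency(tr), 2 / 3)
  expect_error(banding_frequency(0), "positive")
  expect_error(passband_halfwidth(-1), "positive")
})

test_that("short-TR limit agrees with the full equation at TR = 2.86 ms", {
  lim <- bssfp_signal_tr0(wm, 40)
  expect_equal(lim, 0.7 * sin(40 * pi / 180) /
                 ((450 / 90) * (1 - cos(40 * pi / 180)) + 1 + cos(40 * pi / 180)))
  expect_equal(lim, 0.153, tolerance = 2e-3)
  tm <- sequence_timing(TR = 2.86, TE1 = 0.1, TE2 = 2.68, alpha = 40)
  full <- Mod(bssfp_signal(wm, tm, 0, TE = 0))
  expect_lt(abs(full - lim) / lim, 0.02)
})

test_that("flip-angle matching solves the signal equality", {
  a <- match_flip_angle(aqueous, wm, 40)
  expect_equal(round(a), 18)
  # residual of the matching equality
  expect_lt(abs(bssfp_signal_tr0(aqueous, a) - bssfp_signal_tr0(wm, 40)) /
              bssfp_signal_tr0(wm, 40), 1e-6)
  # identity case
  expect_equal(match_flip_angle(wm, wm, 37), 37, tolerance = 1e-6)
  # unreachable target
  dim_tissue <- tissue_params(1000, 50, PD = 0.05)
  expect_error(match_flip_angle(dim_tissue, wm, 40), "no flip angle")
})

test_that("flip-angle matching agrees with the 0.01-degree grid oracle", {
  set.seed(42)
  n_ok <- 0
  while (n_ok < 100) {
    T1r <- runif(1, 200, 3000); T2r <- runif(1, 30, min(T1r, 1500))
    T1p <- runif(1, 100, 3000); T2p <- runif(1, 30, min(T1p, 1500))
    ref <- tissue_params(T1r, T2r, runif(1, 0.3, 1))
    ph <- tissue_params(T1p, T2p, runif(1, 0.3, 1))
    aref <- runif(1, 15, 70)
    solved <- tryCatch(match_flip_angle(ph, ref, aref), error = function(e) NULL)
    if (is.null(solved)) next
    n_ok <- n_ok + 1
    # the equality can have two roots; the solver must land on one of the
    # grid-scan solutions
    expect_lt(min(abs(solved - grid_search_flip_all(ph, ref, aref))), 0.05)
  }
})

test_that("MT weighting is the stated depletion and rejects bad MTR", {
  expect_equal(mt_weighted_signal(1.5, 0), 1.5)
  expect_equal(mt_weighted_signal(1.5, 100), 0)
  expect_equal(mt_weighted_signal(1.0, 43.3), 0.567)
  expect_error(mt_weighted_signal(1, -2), "percent units")
  expect_error(mt_weighted_signal(1, 101), "percent units")
})

test_that("SPGR signal has the ideal-spoiling magnitude and exact TE phase", {
  expect_equal(Mod(spgr_signal(wm, 17, 4, 1e-9, 0)), 0, tolerance = 1e-9)
  s <- spgr_signal(wm, 17, 4, 15, off_res_hz = 50)
  expect_equal(Arg(s), 2 * pi * 50 * 4e-3, tolerance = 1e-12)
  s2 <- spgr_signal(wm, 17, 12, 15, off_res_hz = 50)
  dphi <- Arg(s2 * Conj(s))
  expect_equal(dphi, 2.513, tolerance = 1e-3)  # 2 pi * 50 Hz * 8 ms
  # magnitude: closed form
  E1 <- exp(-17 / 450)
  a <- 15 * pi / 180
  expect_equal(Mod(s), 0.7 * sin(a) * (1 - E1) / (1 - E1 * cos(a)) *
                 exp(-4 / 90), tolerance = 1e-12)
})

test_that("voxel-volume SNR penalty reproduces the resolution cube law", {
  expect_equal(voxel_snr_penalty(0.69, 0.87), (0.69 / 0.87)^3)
  expect_error(voxel_snr_penalty(0, 1), "positive")
})
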