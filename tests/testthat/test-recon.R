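test_that("adjoint reconstruction localizes a point object", {
  ph <- tiny_phantom(32, voxel = 6, single_voxel = TRUE, PD = 1)
  proto <- proto2d(n = 32, R = 1)
  traj <- build_bstar_trajectory(proto, ndim = 2)
  k <- simulate_bstar(ph, traj, proto, noise_sd = 0)
  img <- adjoint_recon(k, c(32L, 32L), 192, echo = 1)
  expect_equal(which.max(Mod(img$data)),
               which.max(ph$PD))
  # zero k-space reconstructs to zero
  k0 <- k; k0$samples[] <- 0i
  expect_equal(max(Mod(adjoint_recon(k0, c(32L, 32L), 192, echo = 1)$data)), 0)
})

test_that("multi-coil adjoint without maps warns and falls back to RSS", {
  k <- kspace64()
  expect_warning(img <- adjoint_recon(k, c(64L, 64L), 192, echo = 1),
                 "root-sum-of-squares")
  expect_false(is.complex(img$data))
})

test_that("coil maps estimated from data recover the simulated maps", {
  k <- kspace64()
  maps <- estimate_coil_sensitivities(k, c(64L, 64L), 192,
                                      calib_radius = 0.3)
  truth <- coils64()
  ph <- brain64_onres()
  # pure-tissue voxels: support-edge partial volumes carry ringing from
  # the low-resolution calibration, not sensitivity information
  interior <- (ph$frac$wm + ph$frac$gm + ph$frac$csf) == 1
  for (ci in 1:6) {
    m_est <- Mod(maps[, , ci])[interior]
    m_true <- Mod(truth[, , ci])[interior]
    expect_gt(stats::cor(m_est, m_true), 0.98)
  }
  # single uniform coil: map is ~1 on the support
  ph1 <- tiny_phantom(32, voxel = 6, PD = 1)
  ph1$PD[c(1:8, 25:32), ] <- 0
  proto <- proto2d(n = 32, R = 1)
  traj <- build_bstar_trajectory(proto, ndim = 2)
  k1 <- simulate_bstar(ph1, traj, proto, noise_sd = 0)
  m1 <- estimate_coil_sensitivities(k1, c(32L, 32L), 192,
                                    calib_radius = 0.5)
  inner <- ph1$PD > 0
  inner[c(9:10, 23:24), ] <- FALSE  # exclude the sharp support edge
  expect_lt(max(abs(Mod(m1[, , 1])[inner] - 1)), 0.05)
  expect_error(estimate_coil_sensitivities(k1, c(32L, 32L), 192,
                                           calib_radius = 0), "calib_radius")
  k1$samples[] <- 0i
  expect_error(estimate_coil_sensitivities(k1, c(32L, 32L), 192),
               "degenerate")
})

test_that("coil-map reuse between non-MT and MT scans is intensity-safe", {
  ph <- brain64_onres()
  cm <- coils64()
  traj <- traj64()
  p_mt <- proto2d("hr_mt")
  k_mt <- simulate_bstar(ph, traj, p_mt, mt_weighted = TRUE, noise_sd = 0,
                         seed = 4, coil_maps = cm)
  maps_non <- maps64()  # estimated on the non-MT twin
  maps_mt <- estimate_coil_sensitivities(k_mt, c(64L, 64L), 192)
  rec <- function(maps) Mod(adjoint_recon(k_mt, c(64L, 64L), 192,
                                          coil_maps = maps, echo = 1)$data)
  a <- rec(maps_non); b <- rec(maps_mt)
  supp <- phantom_mask(ph)
  expect_lt(sqrt(mean((a[supp] - b[supp])^2)) / sqrt(mean(b[supp]^2)), 0.02)
})

test_that("unregularized FISTA reaches the least-squares solution", {
  # fully sampled Cartesian-equivalent trajectory: the LS solution is the
  # simulated image itself
  grid <- c(16L, 16L, 16L); fov <- 32
  kk <- as.matrix(expand.grid(seq_len(16) - 9, seq_len(16) - 9,
                              seq_len(16) - 9)) / fov
  n_half <- 256L; n_samp <- 16L
  traj <- structure(list(coords = kk, echo = rep(1L, n_half),
                         radius = sqrt(rowSums(kk^2)), kmax = 8 / fov,
                         n_half = n_half, n_samp = n_samp, ndim = 3L,
                         dcf = rep(1, 4096)), class = "bstar_trajectory")
  set.seed(21)
  x_true <- array(0i, grid)
  x_true[5:12, 5:12, 5:12] <- complex(real = runif(512), imaginary = 0)
  y <- nufft_forward(nufft_plan(kk, grid, fov, width = 8), x_true)
  k <- kspace_data(matrix(y, ncol = 1), traj)
  cfg <- recon_config(n_iterations = 50, lambda_reg = 0, width = 8)
  img <- fista_recon(k, grid, fov, config = cfg, echo = 1)
  nrmse <- sqrt(mean(Mod(img$data - x_true)^2)) / sqrt(mean(Mod(x_true)^2))
  expect_lt(nrmse, 0.01)
})

test_that("monotone FISTA never increases the objective", {
  k <- kspace64()
  img <- fista_recon(k, c(64L, 64L), 192, coil_maps = maps64(),
                     config = recon_config(n_iterations = 12,
                                           lambda_reg = 0.05), echo = 1)
  o <- img$provenance$objective
  expect_length(o, 12)
  expect_true(all(diff(o) <= 1e-9 * o[1]))
})

test_that("reconstruction is deterministic and scaling-equivariant", {
  k <- kspace64()
  cfg <- recon_config(n_iterations = 4)
  r1 <- fista_recon(k, c(64L, 64L), 192, coil_maps = maps64(),
                    config = cfg, echo = 1)
  r2 <- fista_recon(k, c(64L, 64L), 192, coil_maps = maps64(),
                    config = cfg, echo = 1)
  expect_identical(r1$data, r2$data)
  kc <- k; kc$samples <- 3.7 * k$samples
  r3 <- fista_recon(kc, c(64L, 64L), 192, coil_maps = maps64(),
                    config = cfg, echo = 1)
  expect_equal(r3$data, 3.7 * r1$data, tolerance = 1e-9)
})

test_that("compressed sensing is no worse than gridding on the brain sim", {
  ph <- brain64_onres()
  cm <- coils64()
  traj <- traj64()
  proto <- proto2d()
  grid <- c(64L, 64L)
  nsd <- calibrate_noise_sd(traj, grid, 192, 0.5, 20, coil_maps = cm)
  k <- simulate_bstar(ph, traj, proto, noise_sd = nsd, seed = 8,
                      coil_maps = cm)
  maps <- estimate_coil_sensitivities(k, grid, 192)
  truth <- Mod(bssfp_signal(ph, proto$timing, off_res_hz = ph$off_res,
                            TE = proto$timing$TE1))
  supp <- phantom_mask(ph)
  nrmse <- function(img) {
    m <- Mod(img$data)
    sc <- sum(m[supp] * truth[supp]) / sum(m[supp]^2)
    sqrt(mean((sc * m[supp] - truth[supp])^2)) / sqrt(mean(truth[supp]^2))
  }
  adj <- adjoint_recon(k, grid, 192, coil_maps = maps, echo = 1)
  cs <- fista_recon(k, grid, 192, coil_maps = maps,
                    config = recon_config(), echo = 1)
  expect_lte(nrmse(cs), nrmse(adj))
})

test_that("echo combination adds complex volumes with safeguards", {
  a <- image_volume(array(1 + 1i, c(4, 4)), 1)
  b <- image_volume(array(0i, c(4, 4)), 1)
  expect_equal(combine_echoes(a, b)$data, a$data)
  expect_equal(Mod(combine_echoes(a, a)$data), 2 * Mod(a$data))
  # pi inter-echo phase cancels: f = 1/(2 dTE) with the HR echo times
  p <- proto2d()
  dte <- (p$timing$TE2 - p$timing$TE1) * 1e-3
  f_pi <- 1 / (2 * dte)
  e1 <- array(exp(2i * pi * f_pi * p$timing$TE1 * 1e-3), c(2, 2))
  e2 <- array(exp(2i * pi * f_pi * p$timing$TE2 * 1e-3), c(2, 2))
  comb <- combine_echoes(image_volume(e1, 1), image_volume(e2, 1))
  expect_lt(max(Mod(comb$data)), 1e-12)
  expect_error(combine_echoes(a, image_volume(array(0i, c(2, 2)), 1)),
               "same grid")
})
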