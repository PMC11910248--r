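#' Simulated k-space data container
#'
#' Complex samples indexed by (coil, half-projection, sample), stored as
#' a `[n_samp * n_half, n_coils]` matrix in trajectory sample order
#' (sample index fastest), together with the trajectory, noise level and
#' seed so a simulation is fully reproducible from its own record.
#'
#' @param samples Complex matrix `[n_samp * n_half, n_coils]`.
#' @param traj The `bstar_trajectory` the samples live on.
#' @param noise_sd Per-sample complex-channel noise standard deviation.
#' @param seed Integer seed used for the noise stream.
#' @param meta Optional provenance list.
#' @return A `kspace_data` object.
#' @export
kspace_data <- function(samples, traj, noise_sd = 0, seed = NA_integer_,
                        meta = list()) {
  samples <- as.matrix(samples)
  if (nrow(samples) != traj$n_half * traj$n_samp)
    stop("sample count does not match the trajectory")
  structure(list(samples = samples, traj = traj, noise_sd = noise_sd,
                 seed = seed, n_coils = ncol(samples), meta = meta),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf("kspace_data: %d coils x %d half-projections x %d samples, noise_sd = %g\n",
              x$n_coils, x$traj$n_half, x$traj$n_samp, x$noise_sd))
  invisible(x)
}

# rows of the sample matrix belonging to one echo
.echo_rows <- function(traj, echo) {
  hp <- which(traj$echo == echo)
  as.vector(outer(seq_len(traj$n_samp), (hp - 1L) * traj$n_samp, `+`))
}

# readout duration of one half-projection (ms): samples / (BW/px * matrix)
.readout_half_ms <- function(protocol) {
  m <- protocol_matrix(protocol)
  protocol$samples_per_half_projection /
    (protocol$bandwidth_hz_per_px * m) * 1e3
}

#' Simulate bSTAR dual-echo k-space from a digital phantom
#'
#' Per-voxel steady-state magnetization is computed with
#' [bssfp_signal()] at the echo time of each half-projection's k = 0
#' crossing (TE1 for center-out, TE2 for center-in), multiplied by
#' `(1 - mtr_true/100)` when MT weighting is requested, weighted by the
#' coil sensitivities and transformed to the non-uniform samples with
#' the gridding NUFFT. Off-resonance accrues additional per-sample phase
#' `2 pi f (t - TE)` along the readout, with
#' `t = TE +/- (r/kmax) * T_half` and `T_half` the half-projection
#' readout duration derived from samples/bandwidth; this is applied by
#' time segmentation with an interpolation node pinned at the echo
#' (`t = TE`), so the k = 0 crossing is exact. Complex Gaussian noise of
#' standard deviation `noise_sd` per real/imaginary channel is added
#' from the seed.
#'
#' @param phantom A `digital_phantom` (voxel size must not exceed the
#'   protocol's nominal resolution).
#' @param traj A `bstar_trajectory` for the same geometry.
#' @param protocol A [protocol_params()].
#' @param mt_weighted Apply the phenomenological MT depletion?
#' @param noise_sd Complex noise standard deviation (0 = noiseless).
#' @param seed Integer seed for the noise stream.
#' @param coil_maps Complex array `c(dim(phantom$PD), n_coils)`; default
#'   `phantom$coil_maps`, or a single uniform coil when absent.
#' @param n_time_seg Number of off-resonance time-segmentation nodes per
#'   echo (default 6).
#' @param width,oversamp NUFFT accuracy parameters (defaults width 8,
#'   oversampling 2: ~1e-7 relative accuracy).
#' @return A [kspace_data()] object.
#' @export
simulate_bstar <- function(phantom, traj, protocol, mt_weighted = FALSE,
                           noise_sd = 0, seed = 1,
                           coil_maps = phantom$coil_maps,
                           n_time_seg = 6, width = 8, oversamp = 2) {
  n <- dim(phantom$PD)
  if (length(n) != traj$ndim)
    stop("phantom and trajectory dimensionality differ")
  if (1 / (2 * phantom$voxel_size) < traj$kmax * (1 - 1e-9))
    stop("phantom voxel size is coarser than the trajectory resolution")
  if (is.null(coil_maps)) coil_maps <- array(1 + 0i, c(n, 1L))
  cm_dim <- dim(coil_maps)
  if (!all(cm_dim[seq_along(n)] == n))
    stop("coil map grid does not match the phantom grid")
  n_coils <- cm_dim[length(cm_dim)]
  fov <- n * phantom$voxel_size
  timing <- protocol$timing
  t_half <- .readout_half_ms(protocol)
  samples <- matrix(0i, traj$n_half * traj$n_samp, n_coils)
  for (echo in 1:2) {
    te <- if (echo == 1) timing$TE1 else timing$TE2
    img <- bssfp_signal(phantom, timing, off_res_hz = phantom$off_res,
                        TE = te)
    if (mt_weighted) img <- mt_weighted_signal(img, phantom$mtr_true)
    rows <- .echo_rows(traj, echo)
    plan <- nufft_plan(traj$coords[rows, , drop = FALSE], n, fov,
                       oversamp = oversamp, width = width)
    # time from the echo along the readout, per sample of this echo
    sgn <- if (echo == 1) 1 else -1
    tau <- sgn * (traj$radius[rows] / traj$kmax) * t_half
    rng <- range(tau)
    nodes <- if (n_time_seg <= 1 || diff(rng) == 0) 0
             else seq(rng[1], rng[2], length.out = n_time_seg)
    if (!0 %in% nodes) nodes <- sort(c(0, nodes))
    # linear interpolation weights onto the nodes
    wts <- matrix(0, length(tau), length(nodes))
    if (length(nodes) == 1) {
      wts[, 1] <- 1
    } else {
      iv <- findInterval(tau, nodes, rightmost.closed = TRUE)
      iv <- pmin(pmax(iv, 1L), length(nodes) - 1L)
      frac <- (tau - nodes[iv]) / (nodes[iv + 1] - nodes[iv])
      wts[cbind(seq_along(tau), iv)] <- 1 - frac
      wts[cbind(seq_along(tau), iv + 1L)] <- wts[cbind(seq_along(tau), iv + 1L)] + frac
    }
    for (c_i in seq_len(n_coils)) {
      cw <- if (traj$ndim == 2) coil_maps[, , c_i] else coil_maps[, , , c_i]
      acc <- complex(length(rows))
      for (l in seq_along(nodes)) {
        mod <- img * cw * exp(1i * 2 * pi * phantom$off_res * nodes[l] * 1e-3)
        acc <- acc + wts[, l] * nufft_forward(plan, mod)
      }
      samples[rows, c_i] <- acc
    }
  }
  if (noise_sd > 0) {
    samples <- samples + with_local_seed(seed, {
      nr <- length(samples)
      matrix(complex(real = stats::rnorm(nr, 0, noise_sd),
                     imaginary = stats::rnorm(nr, 0, noise_sd)),
             nrow(samples), ncol(samples))
    })
  }
  kspace_data(samples, traj, noise_sd = noise_sd, seed = seed,
              meta = list(protocol = protocol$label,
                          mt_weighted = mt_weighted,
                          t_half_ms = t_half, n_time_seg = n_time_seg))
}

#' Simulate a dual-echo SPGR acquisition for B0 mapping
#'
#' Voxelwise ideally spoiled SPGR signal at two echo times in the image
#' domain (Cartesian), with phase `2 pi f TE` from the phantom's
#' off-resonance field and optional complex Gaussian noise. T2* is
#' modeled as T2.
#'
#' @param phantom A `digital_phantom`.
#' @param TE_pair The two echo times (ms), `TE1 < TE2`; default the
#'   published 4 / 12 ms.
#' @param TR Repetition time (ms), default 17.
#' @param alpha Flip angle (degrees), default 15.
#' @param noise_sd Complex noise standard deviation.
#' @param seed Integer seed.
#' @return List with complex volumes `echo1`, `echo2` and `TE_pair`.
#' @export
simulate_b0_scan <- function(phantom, TE_pair = c(4, 12), TR = 17,
                             alpha = 15, noise_sd = 0, seed = 1) {
  if (!(TE_pair[1] < TE_pair[2])) stop("TE_pair must satisfy TE1 < TE2")
  vols <- lapply(TE_pair, function(te)
    spgr_signal(phantom, TR = TR, TE = te, alpha = alpha,
                off_res_hz = phantom$off_res))
  if (noise_sd > 0) {
    vols <- with_local_seed(seed, lapply(vols, function(v) {
      v + array(complex(real = stats::rnorm(length(v), 0, noise_sd),
                        imaginary = stats::rnorm(length(v), 0, noise_sd)),
                dim(v))
    }))
  }
  list(echo1 = vols[[1]], echo2 = vols[[2]], TE_pair = TE_pair)
}

#' Calibrate the k-space noise level for a target image SNR
#'
#' The adjoint reconstruction is linear, so the k-space-to-image noise
#' gain can be measured once: a unit-variance complex-noise k-space is
#' reconstructed and the voxelwise magnitude standard deviation taken in
#' a background region. The returned `noise_sd` then yields an apparent
#' image SNR of approximately `target_snr` for voxels at
#' `signal_level` magnitude in the matching adjoint reconstruction.
#'
#' @param traj A `bstar_trajectory`.
#' @param grid Image grid size.
#' @param fov_mm Field of view (mm).
#' @param signal_level Reference image signal magnitude (e.g. median
#'   white-matter magnitude of a noiseless reconstruction).
#' @param target_snr Desired apparent SNR.
#' @param coil_maps Optional coil maps used by the reconstruction.
#' @param echo Echo used for the probe reconstruction (default 1).
#' @param seed Seed for the probe noise.
#' @return The calibrated `noise_sd`.
#' @export
calibrate_noise_sd <- function(traj, grid, fov_mm, signal_level,
                               target_snr, coil_maps = NULL, echo = 1,
                               seed = 99) {
  n_coils <- if (is.null(coil_maps)) 1L else dim(coil_maps)[length(dim(coil_maps))]
  probe <- with_local_seed(seed, {
    nr <- traj$n_half * traj$n_samp
    matrix(complex(real = stats::rnorm(nr * n_coils),
                   imaginary = stats::rnorm(nr * n_coils)), nr, n_coils)
  })
  k <- kspace_data(probe, traj, noise_sd = 1, seed = seed)
  img <- adjoint_recon(k, grid = grid, fov_mm = fov_mm,
                       coil_maps = coil_maps, echo = echo)
  gain <- stats::sd(Mod(img$data))
  signal_level / (target_snr * gain)
}
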