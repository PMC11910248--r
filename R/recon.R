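#' Image volume container
#'
#' @param data Complex (or numeric) voxel array.
#' @param voxel_size Isotropic voxel size (mm).
#' @param provenance Named list (protocol id, echo tag or "combined",
#'   iteration count, lambda, ...).
#' @return An `image_volume` object.
#' @export
image_volume <- function(data, voxel_size, provenance = list()) {
  structure(list(data = data, voxel_size = voxel_size,
                 provenance = provenance), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume: %s voxels @ %g mm (%s)\n",
              paste(dim(x$data), collapse = "x"), x$voxel_size,
              paste(names(x$provenance),
                    vapply(x$provenance, function(v) paste(format(v), collapse = ","), ""),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Reconstruction configuration
#'
#' @param n_iterations FISTA iteration count (`>= 1`), default 12.
#' @param lambda_reg Regularization weight, `>= 0`, interpreted relative
#'   to the maximum magnitude of the (Lipschitz-scaled) adjoint image;
#'   default 0.05.
#' @param matrix Reconstruction grid size per axis.
#' @param transform Sparsity transform label (only `"db4"`).
#' @param levels Wavelet decomposition depth.
#' @param oversamp,width NUFFT settings used by the reconstruction.
#' @return A `recon_config` object.
#' @export
recon_config <- function(n_iterations = 12, lambda_reg = 0.05,
                         matrix = NULL, transform = "db4", levels = 3,
                         oversamp = 2, width = 5) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (lambda_reg < 0) stop("lambda_reg must be >= 0")
  if (!identical(transform, "db4"))
    stop("unknown sparsity transform: ", transform)
  structure(list(n_iterations = as.integer(n_iterations),
                 lambda_reg = lambda_reg, matrix = matrix,
                 transform = transform, levels = levels,
                 oversamp = oversamp, width = width),
            class = "recon_config")
}

.coil_map_list <- function(coil_maps, ndim) {
  nc <- dim(coil_maps)[ndim + 1]
  lapply(seq_len(nc), function(c_i)
    if (ndim == 2) coil_maps[, , c_i] else coil_maps[, , , c_i])
}

#' Density-compensated adjoint (gridding) reconstruction
#'
#' Adjoint NUFFT of the density-compensation-weighted samples, combined
#' across coils with conjugate sensitivities (normalized by the
#' sum-of-squares sensitivity); without coil maps a root-sum-of-squares
#' combination is used (with a warning for multi-coil data). The image
#' is normalized by the total density-compensation weight so a unit
#' point source reconstructs with unit peak.
#'
#' @param kspace A [kspace_data()] object.
#' @param grid Image grid size per axis.
#' @param fov_mm Field of view (mm).
#' @param coil_maps Complex sensitivity array `c(grid, n_coils)`, or
#'   `NULL`.
#' @param echo Echo to reconstruct (1, 2) or `NULL` for all samples.
#' @param oversamp,width NUFFT settings.
#' @return An `image_volume` (complex for sensitivity combination, real
#'   for RSS).
#' @export
adjoint_recon <- function(kspace, grid, fov_mm, coil_maps = NULL,
                          echo = NULL, oversamp = 2, width = 5) {
  traj <- kspace$traj
  rows <- if (is.null(echo)) seq_len(traj$n_half * traj$n_samp)
          else .echo_rows(traj, echo)
  plan <- nufft_plan(traj$coords[rows, , drop = FALSE], grid, fov_mm,
                     oversamp = oversamp, width = width)
  d <- traj$dcf[rows]
  scale <- 1 / sum(d)
  imgs <- lapply(seq_len(kspace$n_coils), function(c_i)
    nufft_adjoint(plan, d * kspace$samples[rows, c_i]) * scale)
  vox <- fov_mm / grid[1]
  prov <- list(protocol = kspace$meta$protocol %||% NA,
               echo = if (is.null(echo)) "all" else echo,
               method = "adjoint")
  if (is.null(coil_maps)) {
    if (kspace$n_coils > 1)
      warning("no coil maps supplied; falling back to root-sum-of-squares combination")
    if (kspace$n_coils == 1) return(image_volume(imgs[[1]], vox, prov))
    rss <- sqrt(Reduce(`+`, lapply(imgs, function(v) Mod(v)^2)))
    return(image_volume(rss, vox, prov))
  }
  sm <- .coil_map_list(coil_maps, traj$ndim)
  num <- Reduce(`+`, Map(function(im, s) Conj(s) * im, imgs, sm))
  den <- Reduce(`+`, lapply(sm, function(s) Mod(s)^2))
  image_volume(num / pmax(den, 1e-8 * max(den)), vox, prov)
}

#' Estimate coil sensitivity maps from the k-space center
#'
#' Low-resolution per-coil images are formed from a Hann-windowed
#' central k-space disc (radius `calib_radius * kmax`) and divided by
#' their root-sum-of-squares, yielding smooth maps with RSS = 1 on the
#' object support. Intended to be estimated once (e.g. on the non-MT
#' scan) and reused for the matching MT-weighted reconstruction so no
#' intensity bias enters the MTR.
#'
#' @param kspace A [kspace_data()] object.
#' @param grid Image grid size.
#' @param fov_mm Field of view (mm).
#' @param calib_radius Calibration radius as a fraction of kmax, in
#'   (0, 1].
#' @param echo Echo used for calibration (default 1).
#' @param mask_frac Support threshold as a fraction of the maximum RSS
#'   (maps are zero outside).
#' @param oversamp,width NUFFT settings.
#' @return Complex array `c(grid, n_coils)`.
#' @export
estimate_coil_sensitivities <- function(kspace, grid, fov_mm,
                                        calib_radius = 0.15, echo = 1,
                                        mask_frac = 0.05,
                                        oversamp = 2, width = 5) {
  if (!(calib_radius > 0 && calib_radius <= 1))
    stop("calib_radius must lie in (0, 1]")
  traj <- kspace$traj
  rows <- .echo_rows(traj, echo)
  r <- traj$radius[rows]
  rcal <- calib_radius * traj$kmax
  win <- ifelse(r < rcal, cos(pi * r / (2 * rcal))^2, 0)
  wd <- win * traj$dcf[rows]
  if (all(Mod(kspace$samples[rows, , drop = FALSE][wd > 0, , drop = FALSE]) == 0))
    stop("degenerate calibration region: no signal inside calib_radius")
  plan <- nufft_plan(traj$coords[rows, , drop = FALSE], grid, fov_mm,
                     oversamp = oversamp, width = width)
  imgs <- lapply(seq_len(kspace$n_coils), function(c_i)
    nufft_adjoint(plan, wd * kspace$samples[rows, c_i]))
  rss <- sqrt(Reduce(`+`, lapply(imgs, function(v) Mod(v)^2)))
  supp <- rss > mask_frac * max(rss)
  maps <- array(0i, c(grid, kspace$n_coils))
  idx <- as.list(rep(TRUE, length(grid)))
  for (c_i in seq_len(kspace$n_coils)) {
    m <- imgs[[c_i]] / pmax(rss, .Machine$double.eps)
    m[!supp] <- 0i
    maps <- do.call(`[<-`, c(list(maps), idx, list(c_i), list(m)))
  }
  maps
}

#' Wavelet-regularized FISTA compressed-sensing reconstruction
#'
#' Minimizes `1/2 ||sqrt(D)(A x - y)||^2 + lambda ||W x||_1` where `A`
#' is the coil-weighted NUFFT of one echo, `D` the radial
#' density-compensation weights (preconditioning the radial sampling so
#' few iterations suffice), and `W` the orthonormal Daubechies-4
#' wavelet. The monotone FISTA variant is used, so the objective is
#' non-increasing by construction; the Lipschitz constant is estimated
#' by power iteration on `A^H D A`. `lambda_reg` is scaled by the
#' maximum magnitude of the initial (adjoint) image, making the
#' reconstruction equivariant under global scaling of the data.
#'
#' @param kspace A [kspace_data()] object.
#' @param grid Image grid size (overridden by `config$matrix` if set).
#' @param fov_mm Field of view (mm).
#' @param coil_maps Complex sensitivities `c(grid, n_coils)`; `NULL`
#'   for a single uniform coil.
#' @param config A [recon_config()].
#' @param echo Echo to reconstruct (default 1).
#' @param power_iters,power_tol Power-iteration budget and relative
#'   tolerance for the Lipschitz estimate.
#' @return An `image_volume`; `$provenance$objective` holds the
#'   per-iteration objective values.
#' @export
fista_recon <- function(kspace, grid, fov_mm, coil_maps = NULL,
                        config = recon_config(), echo = 1,
                        power_iters = 30, power_tol = 1e-3) {
  traj <- kspace$traj
  grid <- config$matrix %||% grid
  rows <- .echo_rows(traj, echo)
  plan <- nufft_plan(traj$coords[rows, , drop = FALSE], grid, fov_mm,
                     oversamp = config$oversamp, width = config$width)
  d <- traj$dcf[rows]
  if (is.null(coil_maps)) coil_maps <- array(1 + 0i, c(grid, kspace$n_coils))
  sm <- .coil_map_list(coil_maps, traj$ndim)
  y <- lapply(seq_len(kspace$n_coils), function(c_i)
    kspace$samples[rows, c_i])
  A <- function(x) lapply(sm, function(s) nufft_forward(plan, s * x))
  AH <- function(ys) Reduce(`+`, Map(function(s, yc)
    Conj(s) * nufft_adjoint(plan, d * yc), sm, ys))
  # Lipschitz constant of x -> AH(D A x) by power iteration
  v <- AH(y)
  nv <- sqrt(sum(Mod(v)^2))
  if (nv == 0) v <- array(1 + 0i, grid) else v <- v / nv
  L <- NA
  for (it in seq_len(power_iters)) {
    w <- AH(A(v))
    Lnew <- sqrt(sum(Mod(w)^2))
    if (Lnew == 0) stop("power iteration degenerate (zero operator)")
    v <- w / Lnew
    if (!is.na(L) && abs(Lnew - L) < power_tol * Lnew) { L <- Lnew; break }
    L <- Lnew
  }
  if (is.na(L) || !is.finite(L))
    stop("power iteration for the Lipschitz constant did not converge")
  L <- 1.02 * L
  # initialize from the adjoint image with the optimal least-squares
  # amplitude, argmin_a ||sqrt(D)(A(a x_adj) - y)||
  x0 <- AH(y)
  Ax0 <- A(x0)
  den0 <- sum(vapply(seq_along(Ax0), function(i)
    sum(d * Mod(Ax0[[i]])^2), numeric(1)))
  if (den0 > 0) {
    num0 <- sum(vapply(seq_along(Ax0), function(i)
      Re(sum(d * Conj(Ax0[[i]]) * y[[i]])), numeric(1)))
    x0 <- x0 * (num0 / den0)
  }
  lam <- config$lambda_reg * max(Mod(x0))
  obj <- function(x, Ax = A(x)) {
    fid <- 0.5 * sum(vapply(seq_along(Ax), function(i)
      sum(d * Mod(Ax[[i]] - y[[i]])^2), numeric(1)))
    fid + lam * sum(Mod(dwt_db4(x, config$levels)))
  }
  prox <- function(x) {
    w <- dwt_db4(x, config$levels)
    lv <- attr(w, "levels")
    mag <- Mod(w)
    shrink <- pmax(mag - lam / L, 0) / pmax(mag, .Machine$double.eps)
    w <- w * shrink
    attr(w, "levels") <- lv
    idwt_db4(w)
  }
  x <- x0
  z <- x0
  t_k <- 1
  F_x <- obj(x)
  objective <- numeric(config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    Az <- A(z)
    grad <- AH(Map(`-`, Az, y))
    u <- prox(z - grad / L)
    F_u <- obj(u)
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    if (F_u <= F_x) {
      x_new <- u; F_new <- F_u
    } else {
      x_new <- x; F_new <- F_x   # monotone step: keep the best iterate
    }
    z <- x_new + (t_k / t_next) * (u - x_new) +
      ((t_k - 1) / t_next) * (x_new - x)
    x <- x_new; F_x <- F_new; t_k <- t_next
    objective[it] <- F_x
  }
  image_volume(x, fov_mm / grid[1],
               provenance = list(protocol = kspace$meta$protocol %||% NA,
                                 echo = echo, method = "fista",
                                 iterations = config$n_iterations,
                                 lambda = config$lambda_reg,
                                 lambda_abs = lam, L = L,
                                 objective = objective))
}

#' Complex combination of the two echo reconstructions
#'
#' The separately reconstructed center-out and center-in images are
#' added in complex space; by the triangle inequality the combined
#' magnitude never exceeds the sum of the parts, and an inter-echo phase
#' of pi (off-resonance `1/(2 (TE2 - TE1))`) cancels destructively.
#'
#' @param echo1,echo2 `image_volume`s on the same grid.
#' @return Combined `image_volume`.
#' @export
combine_echoes <- function(echo1, echo2) {
  if (!all(dim(echo1$data) == dim(echo2$data)))
    stop("echo volumes must share the same grid")
  image_volume(echo1$data + echo2$data, echo1$voxel_size,
               provenance = utils::modifyList(echo1$provenance,
                                              list(echo = "combined")))
}
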