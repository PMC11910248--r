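# Digital phantom generators. All generators are pure functions of
# (parameters, seed): randomness is drawn from a local RNG stream that
# does not disturb the caller's RNG state.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# block-average an array by integer factor f per axis
.downsample_mean <- function(a, f) {
  d <- dim(a)
  nd <- length(d)
  out_d <- d %/% f
  if (nd == 2) {
    dim(a) <- c(f, out_d[1], f, out_d[2])
    a <- aperm(a, c(1, 3, 2, 4))
    dim(a) <- c(f * f, out_d[1] * out_d[2])
    out <- colMeans(a)
    dim(out) <- out_d
  } else {
    dim(a) <- c(f, out_d[1], f, out_d[2], f, out_d[3])
    a <- aperm(a, c(1, 3, 5, 2, 4, 6))
    dim(a) <- c(f^3, prod(out_d))
    out <- colMeans(a)
    dim(out) <- out_d
  }
  out
}

# coordinate grids (mm, centered) for a fine (supersampled) lattice
.fine_coords <- function(n, voxel, super) {
  nf <- n * super
  vf <- voxel / super
  lapply(seq_along(n), function(i)
    (seq_len(nf[i]) - (nf[i] + 1) / 2) * vf)
}

# paint primitives (in order) onto an integer label array
.paint_labels <- function(coords, shapes) {
  nd <- length(coords)
  grids <- if (nd == 2) {
    list(outer(coords[[1]], rep(1, length(coords[[2]]))),
         outer(rep(1, length(coords[[1]])), coords[[2]]))
  } else {
    n <- vapply(coords, length, 1L)
    list(array(coords[[1]], n),
         array(rep(coords[[2]], each = n[1]), n),
         array(rep(coords[[3]], each = n[1] * n[2]), n))
  }
  lab <- array(0L, dim = vapply(coords, length, 1L))
  for (s in shapes) {
    inside <- switch(
      s$type,
      ellipsoid = {
        q <- 0
        for (i in seq_len(nd))
          q <- q + ((grids[[i]] - s$center[i]) / s$semiaxes[i])^2
        q <= 1
      },
      box = {
        inb <- TRUE
        for (i in seq_len(nd))
          inb <- inb & abs(grids[[i]] - s$center[i]) <= s$halfwidth[i]
        inb
      },
      rod = {  # circular cross-section in the first two axes
        q <- ((grids[[1]] - s$center[1])^2 + (grids[[2]] - s$center[2])^2)
        inb <- q <= (s$diameter / 2)^2
        if (nd == 3) inb <- inb & abs(grids[[3]] - s$center[3]) <= s$halflen
        inb
      },
      stop("unknown shape type: ", s$type))
    lab[inside] <- s$label
  }
  lab
}

.assemble_phantom <- function(lab_fine, super, voxel_size, tissues, meta,
                              off_res = NULL) {
  n <- dim(lab_fine) %/% super
  fracs <- lapply(tissues$label, function(l)
    .downsample_mean(array(as.numeric(lab_fine == l), dim(lab_fine)), super))
  names(fracs) <- tissues$name
  # majority label per voxel (background 0 wins only if no tissue covers more)
  frac_stack <- vapply(fracs, as.vector, numeric(prod(n)))
  best <- max.col(frac_stack, ties.method = "first")
  covered <- rowSums(frac_stack) > 0
  label <- array(ifelse(covered, tissues$label[best], 0L), n)
  pick <- function(field, fill) {
    array(ifelse(covered, tissues[[field]][best], fill), n)
  }
  # background relaxation values are benign placeholders; PD = 0 there
  T1 <- pick("T1", 1000); T2 <- pick("T2", 100)
  mtr <- pick("mtr_true", 0)
  # partial-volume mixing goes into PD (signal-space mixing)
  PD <- array(0, n)
  for (i in seq_len(nrow(tissues)))
    PD <- PD + tissues$PD[i] * fracs[[i]]
  structure(list(
    T1 = T1, T2 = T2, PD = PD, mtr_true = mtr,
    off_res = off_res %||% array(0, n),
    label = label, voxel_size = voxel_size,
    tissues = tissues, coil_maps = NULL,
    frac = fracs, meta = meta
  ), class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("digital_phantom '%s': %s voxels @ %g mm, tissues: %s\n",
              x$meta$kind %||% "?",
              paste(dim(x$PD), collapse = "x"), x$voxel_size,
              paste(x$tissues$name, collapse = ", ")))
  invisible(x)
}

#' Resolution-rod phantom (ACR-like)
#'
#' A uniform aqueous disc (T1 = 150 ms, T2 = 100 ms, PD = 1, MTR = 0)
#' containing a signal-free plastic insert drilled with lattices of
#' water-filled resolution rods, one 3x3 lattice per rod diameter with
#' center-to-center spacing twice the diameter (documented choice). The
#' default diameters are 0.9, 0.8 and 0.7 mm, left to right.
#' Rasterization uses 4x-per-axis supersampled partial-volume averaging.
#'
#' @param voxel_size Isotropic voxel size (mm); a warning is issued if it
#'   exceeds the smallest rod diameter.
#' @param rod_diameters Rod diameters (mm), left to right.
#' @param seed Integer seed (generator is deterministic; kept for API
#'   uniformity).
#' @param fov_mm Field of view (mm).
#' @param ndim 2 or 3.
#' @return A `digital_phantom`; `$meta$rod_centers` holds the rod lattice
#'   geometry (mm), `$meta$insert_box` the plastic insert extent.
#' @export
make_resolution_phantom <- function(voxel_size,
                                    rod_diameters = c(0.9, 0.8, 0.7),
                                    seed = 1, fov_mm = 48, ndim = 2) {
  if (length(rod_diameters) == 0) stop("rod_diameters must be non-empty")
  if (voxel_size > min(rod_diameters))
    warning("voxel_size exceeds the smallest rod diameter; rods will not be resolved")
  n <- rep(as.integer(round(fov_mm / voxel_size)), ndim)
  super <- 4L
  tissues <- data.frame(
    label = c(1L, 2L, 3L),
    name = c("water", "plastic", "rod_water"),
    T1 = c(150, 500, 150), T2 = c(100, 50, 100),
    PD = c(1, 0, 1), mtr_true = c(0, 0, 0))
  disc_r <- 0.42 * fov_mm
  shapes <- list(list(type = "ellipsoid", center = rep(0, ndim),
                      semiaxes = rep(disc_r, ndim), label = 1L))
  # rod groups: 3x3 lattices, spacing twice the diameter, laid out along x
  group_w <- vapply(rod_diameters, function(d) 2 * d * 2 + d, 1)
  gap <- 2.5
  total_w <- sum(group_w) + gap * (length(rod_diameters) - 1)
  x0 <- -total_w / 2
  y_row <- -0.5 * disc_r  # lower-middle of the disc
  centers <- NULL
  for (j in seq_along(rod_diameters)) {
    d <- rod_diameters[j]
    cx <- x0 + group_w[j] / 2
    for (ix in -1:1) for (iy in -1:1) {
      centers <- rbind(centers,
                       data.frame(x = cx + ix * 2 * d, y = y_row + iy * 2 * d,
                                  diameter = d, group = j))
    }
    x0 <- x0 + group_w[j] + gap
  }
  insert_half <- c(total_w / 2 + 2, max(2 * max(rod_diameters) * 2, 5))
  insert_center <- c(0, y_row)
  if (ndim == 3) {
    insert_center <- c(insert_center, 0)
    insert_half <- c(insert_half, 0.25 * disc_r)
  }
  shapes <- c(shapes, list(list(type = "box", center = insert_center,
                                halfwidth = insert_half, label = 2L)))
  for (i in seq_len(nrow(centers))) {
    ctr <- c(centers$x[i], centers$y[i])
    if (ndim == 3) ctr <- c(ctr, 0)
    shapes <- c(shapes, list(list(type = "rod", center = ctr,
                                  diameter = centers$diameter[i],
                                  halflen = if (ndim == 3) 0.25 * disc_r else NULL,
                                  label = 3L)))
  }
  lab <- .paint_labels(.fine_coords(n, voxel_size, super), shapes)
  .assemble_phantom(lab, super, voxel_size, tissues,
                    meta = list(kind = "resolution", fov_mm = fov_mm,
                                rod_centers = centers,
                                insert_center = insert_center,
                                insert_half = insert_half,
                                rod_height_mm = if (ndim == 3) 0.5 * disc_r else NA,
                                seed = seed))
}

#' Brain-like digital phantom with MTR ground truth
#'
#' Nested-ellipsoid geometry: an outer CSF shell, a gray-matter shell, a
#' white-matter core and two CSF ventricles. White matter carries the
#' literature values T1 = 450 ms, T2 = 90 ms, PD = 0.7 (relative to an
#' aqueous phantom) and a true MTR of 43.3 pu; GM (T1 = 650, T2 = 100,
#' PD = 0.8, MTR = 38 pu) and CSF (T1 = 3500, T2 = 1500, PD = 1.0,
#' MTR = 2 pu) are documented defaults. A smooth off-resonance field
#' ([make_offres_map()] defaults: 50 Hz bulk, 80 Hz hotspot near the
#' anterior-inferior margin) is attached.
#'
#' @param voxel_size Isotropic voxel size (mm).
#' @param seed Integer seed (drives the off-resonance field).
#' @param fov_mm Field of view (mm).
#' @param ndim 2 or 3.
#' @param offres_peak_hz,offres_bulk_hz Off-resonance field parameters
#'   (Hz); set both to 0 for an on-resonant phantom.
#' @return A `digital_phantom`.
#' @export
make_brain_phantom <- function(voxel_size, seed = 1, fov_mm = 192,
                               ndim = 2, offres_peak_hz = 80,
                               offres_bulk_hz = 50) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  n <- rep(as.integer(round(fov_mm / voxel_size)), ndim)
  super <- 4L
  tissues <- data.frame(
    label = c(1L, 2L, 3L),
    name = c("csf", "gm", "wm"),
    T1 = c(3500, 650, 450), T2 = c(1500, 100, 90),
    PD = c(1.0, 0.8, 0.7), mtr_true = c(2, 38, 43.3))
  f <- fov_mm / 192  # geometry scales with the FOV
  ax <- function(a, b, c3) {
    v <- c(a, b) * f
    if (ndim == 3) c(v, c3 * f) else v
  }
  ctr <- function(x, y, z = 0) {
    v <- c(x, y) * f
    if (ndim == 3) c(v, z * f) else v
  }
  shapes <- list(
    list(type = "ellipsoid", center = ctr(0, 0), semiaxes = ax(86, 66, 72),
         label = 1L),                                   # outer CSF
    list(type = "ellipsoid", center = ctr(0, 0), semiaxes = ax(80, 60, 66),
         label = 2L),                                   # GM shell
    list(type = "ellipsoid", center = ctr(0, 0), semiaxes = ax(68, 48, 54),
         label = 3L),                                   # WM core
    list(type = "ellipsoid", center = ctr(-14, 6), semiaxes = ax(8, 16, 12),
         label = 1L),                                   # ventricles
    list(type = "ellipsoid", center = ctr(14, 6), semiaxes = ax(8, 16, 12),
         label = 1L))
  lab <- .paint_labels(.fine_coords(n, voxel_size, super), shapes)
  off <- if (offres_peak_hz == 0 && offres_bulk_hz == 0) array(0, n)
         else make_offres_map(n, peak_hz = offres_peak_hz,
                              bulk_bound_hz = offres_bulk_hz, seed = seed)
  .assemble_phantom(lab, super, voxel_size, tissues,
                    meta = list(kind = "brain", fov_mm = fov_mm,
                                seed = seed),
                    off_res = off)
}

#' Support mask of a phantom
#'
#' Voxels with any tissue signal (`PD > threshold`).
#'
#' @param phantom A `digital_phantom`.
#' @param threshold PD threshold (default 0.05).
#' @return Logical array.
#' @export
phantom_mask <- function(phantom, threshold = 0.05) {
  phantom$PD > threshold
}

#' Smooth synthetic off-resonance field
#'
#' A low-order harmonic bulk field bounded by `bulk_bound_hz`, blended
#' with one localized Gaussian hotspot (near the anterior-inferior grid
#' margin, emulating the susceptibility focus above the nasal cavity)
#' that reaches `peak_hz` exactly:
#' `field = bulk * (1 - g) + peak_hz * g` with `g` a unit-peak Gaussian.
#'
#' @param shape Integer grid dimensions (length 2 or 3).
#' @param peak_hz Hotspot peak (Hz), `>= bulk_bound_hz`.
#' @param bulk_bound_hz Bound on the bulk field (Hz).
#' @param seed Integer seed for the harmonic coefficients.
#' @param hotspot_sigma_frac Hotspot width as a fraction of the smallest
#'   grid dimension.
#' @return Numeric array of off-resonance (Hz).
#' @export
make_offres_map <- function(shape, peak_hz = 80, bulk_bound_hz = 50,
                            seed = 1, hotspot_sigma_frac = 0.04) {
  if (!(peak_hz >= bulk_bound_hz && bulk_bound_hz >= 0))
    stop("need peak_hz >= bulk_bound_hz >= 0")
  nd <- length(shape)
  if (peak_hz == 0 && bulk_bound_hz == 0) return(array(0, shape))
  co <- lapply(shape, function(m) seq(-1, 1, length.out = m))
  grids <- lapply(seq_len(nd), function(i) {
    perm <- rep(1, nd); perm[i] <- shape[i]
    array(rep(co[[i]], each = prod(shape[seq_len(i - 1)])), shape)
  })
  bulk <- with_local_seed(seed, {
    b <- array(0, shape)
    basis <- list()
    for (i in seq_len(nd)) {
      basis <- c(basis, list(grids[[i]], grids[[i]]^2,
                             cos(pi * grids[[i]]), sin(pi * grids[[i]])))
    }
    if (nd >= 2) basis <- c(basis, list(grids[[1]] * grids[[2]]))
    if (nd == 3) basis <- c(basis, list(grids[[1]] * grids[[3]],
                                        grids[[2]] * grids[[3]]))
    cf <- stats::rnorm(length(basis))
    for (j in seq_along(basis)) b <- b + cf[j] * basis[[j]]
    b
  })
  if (bulk_bound_hz == 0) bulk <- array(0, shape)
  else bulk <- bulk * (bulk_bound_hz / max(abs(bulk)))
  # hotspot near the anterior-inferior margin ("nasal cavity"), snapped
  # to the nearest grid point so the sampled field attains the peak
  hc <- c(0, -0.75, if (nd == 3) -0.4)
  for (i in seq_len(nd)) hc[i] <- co[[i]][which.min(abs(co[[i]] - hc[i]))]
  sigma <- hotspot_sigma_frac * 2  # in normalized coordinates
  d2 <- array(0, shape)
  for (i in seq_len(nd)) d2 <- d2 + (grids[[i]] - hc[i])^2
  g <- exp(-d2 / (2 * sigma^2))
  field <- bulk * (1 - g) + peak_hz * g
  field
}

#' Synthetic multi-channel coil sensitivity maps
#'
#' Smooth complex sensitivities from virtual receive elements arranged
#' on a ring around the field of view, each with a broad Gaussian
#' magnitude profile and a smooth seeded phase. Maps are normalized so
#' the root-sum-of-squares is ~1 in the central object region;
#' `n_coils = 1` returns an exactly uniform map.
#'
#' @param shape Integer grid dimensions (length 2 or 3).
#' @param n_coils Number of receive channels (`>= 1`).
#' @param seed Integer seed (element placement jitter and phases).
#' @return Complex array of dim `c(shape, n_coils)`.
#' @export
make_coil_maps <- function(shape, n_coils, seed = 1) {
  if (n_coils < 1) stop("n_coils must be >= 1")
  nd <- length(shape)
  if (n_coils == 1) return(array(1 + 0i, c(shape, 1)))
  co <- lapply(shape, function(m) seq(-1, 1, length.out = m))
  grids <- lapply(seq_len(nd), function(i)
    array(rep(co[[i]], each = prod(shape[seq_len(i - 1)])), shape))
  maps <- array(0i, c(shape, n_coils))
  with_local_seed(seed, {
    ang0 <- stats::runif(1, 0, 2 * pi)
    jit <- stats::rnorm(n_coils, 0, 0.05)
    ph0 <- stats::runif(n_coils, 0, 2 * pi)
    phg <- matrix(stats::rnorm(n_coils * nd, 0, 0.6), n_coils, nd)
    ring_r <- 1.1
    sigma <- 1.4
    idx <- as.list(rep(TRUE, nd))
    for (c_i in seq_len(n_coils)) {
      th <- ang0 + 2 * pi * (c_i - 1) / n_coils + jit[c_i]
      pc <- c(ring_r * cos(th), ring_r * sin(th),
              if (nd == 3) 0.3 * sin(3 * th))
      d2 <- array(0, shape)
      for (i in seq_len(nd)) d2 <- d2 + (grids[[i]] - pc[i])^2
      phase <- ph0[c_i]
      for (i in seq_len(nd)) phase <- phase + phg[c_i, i] * grids[[i]]
      m <- exp(-d2 / (2 * sigma^2)) * exp(1i * phase)
      maps <- do.call(`[<-`, c(list(maps), idx, list(c_i), list(m)))
    }
  })
  rss <- sqrt(apply(abs(maps)^2, seq_len(nd), sum))
  # scalar normalization over the central region keeps the maps smooth
  ctr <- lapply(shape, function(m)
    seq(max(1, round(m * 0.3)), min(m, round(m * 0.7))))
  scale <- mean(do.call(`[`, c(list(rss), ctr)))
  maps / scale
}
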