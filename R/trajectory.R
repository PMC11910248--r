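#' Near-uniform directions on the sphere along an Archimedean spiral
#'
#' Generalized spiral points: heights `z_i` uniformly spaced in (-1, 1)
#' (cell midpoints) and azimuth advanced by
#' `dphi_i = c / sqrt(n (1 - z_i^2))` with `c = sqrt(n pi)`, giving
#' near-uniform areal density while the polar angle advances
#' monotonically from pole to pole.
#'
#' @param n_points Number of directions (`>= 2`).
#' @return `n_points x 3` matrix of unit vectors (columns x, y, z).
#' @export
archimedean_spiral_directions <- function(n_points) {
  if (n_points < 2) stop("n_points must be at least 2")
  n <- n_points
  z <- -1 + (2 * seq_len(n) - 1) / n
  s <- sqrt(pmax(1 - z^2, 0))
  dphi <- sqrt(n * pi) / sqrt(n * pmax(1 - z^2, 1e-12))
  phi <- cumsum(dphi) - dphi[1]
  cbind(x = s * cos(phi), y = s * sin(phi), z = z)
}

#' Uniform directions on the circle (2D analog)
#'
#' In-plane analog of the spiral direction set for 2D desk-scale
#' experiments: `n_points` angles uniformly covering `[0, 2 pi)`.
#'
#' @param n_points Number of directions (`>= 2`).
#' @return `n_points x 2` matrix of unit vectors.
#' @export
circle_directions <- function(n_points) {
  if (n_points < 2) stop("n_points must be at least 2")
  phi <- 2 * pi * (seq_len(n_points) - 1) / n_points
  cbind(x = cos(phi), y = sin(phi))
}

#' Build the half-radial dual-echo (bSTAR) trajectory
#'
#' Each TR contributes one center-out (echo 1) and one center-in (echo 2)
#' half-projection along consecutive spiral directions: center-out spoke
#' `i` takes direction `2i-1` and its center-in partner direction `2i`
#' (1-based), so a protocol with `n_spokes` TRs yields `2 n_spokes`
#' half-projections of `samples_per_half_projection` samples each.
#' Samples are uniformly spaced in radius from 0 to
#' `kmax = 1/(2 resolution_mm)` cycles/mm; center-in half-projections are
#' stored in time order (edge to center).
#'
#' @param protocol A [protocol_params()] object (uses `n_spokes`,
#'   `samples_per_half_projection`, `resolution_mm`), or `NULL` if the
#'   geometry arguments are given directly.
#' @param n_spokes,samples_per_half,resolution_mm Direct geometry
#'   overrides (used when `protocol` is `NULL`).
#' @param ndim Spatial dimension, 3 (spiral sphere) or 2 (circle analog).
#' @return A `bstar_trajectory` object: list with `coords` (matrix
#'   `[n_half * n_samp, ndim]`, cycles/mm, time-ordered within each
#'   half-projection), `echo` (1 or 2 per half-projection), `radius`
#'   (per sample), `dcf`, `kmax`, `n_half`, `n_samp`, `ndim`.
#' @export
build_bstar_trajectory <- function(protocol = NULL, n_spokes = NULL,
                                   samples_per_half = NULL,
                                   resolution_mm = NULL, ndim = 3) {
  if (!is.null(protocol)) {
    n_spokes <- n_spokes %||% protocol$n_spokes
    samples_per_half <- samples_per_half %||%
      protocol$samples_per_half_projection
    resolution_mm <- resolution_mm %||% protocol$resolution_mm
  }
  if (is.null(n_spokes) || is.null(samples_per_half) ||
      is.null(resolution_mm))
    stop("n_spokes, samples_per_half and resolution_mm are required")
  if (n_spokes < 1 || samples_per_half < 2 || resolution_mm <= 0)
    stop("inconsistent trajectory geometry")
  kmax <- 1 / (2 * resolution_mm)
  n_half <- 2L * as.integer(n_spokes)
  dirs <- if (ndim == 3) archimedean_spiral_directions(n_half)
          else if (ndim == 2) circle_directions(n_half)
          else stop("ndim must be 2 or 3")
  r_out <- seq(0, kmax, length.out = samples_per_half)
  echo <- rep(c(1L, 2L), n_spokes)  # odd rows center-out, even center-in
  # per half-projection: radius in time order
  rad <- matrix(0, samples_per_half, n_half)
  rad[, echo == 1L] <- r_out
  rad[, echo == 2L] <- rev(r_out)
  coords <- matrix(0, n_half * samples_per_half, ndim)
  for (ax in seq_len(ndim)) {
    coords[, ax] <- as.vector(rad * rep(dirs[, ax], each = samples_per_half))
  }
  traj <- structure(list(
    coords = coords, echo = echo,
    radius = as.vector(rad),
    kmax = kmax, n_half = n_half, n_samp = as.integer(samples_per_half),
    ndim = as.integer(ndim), dcf = NULL
  ), class = "bstar_trajectory")
  traj$dcf <- radial_dcf(traj)
  traj
}

#' @export
print.bstar_trajectory <- function(x, ...) {
  cat(sprintf(
    "bstar_trajectory: %d half-projections x %d samples (%dD), kmax = %.4f cycles/mm\n",
    x$n_half, x$n_samp, x$ndim, x$kmax))
  invisible(x)
}

#' Analytic radial density-compensation weights
#'
#' For an ideal radial trajectory the sample density falls as
#' `1/r^(d-1)`; the compensation weight is proportional to `r^(d-1)`
#' (so `r^2` in 3D), with a flat floor below half a radial step whose
#' value is the exact center-cell volume fraction,
#' `dr^(d-1) / (2^d d)` — the k = 0 sample is re-acquired by every
#' half-projection, so its Voronoi cell is the small disc/sphere of
#' radius `dr/2` split among them, 1/8 (2D) or 1/24 (3D) of the first
#' ring's per-sample weight. Weights are normalized to a maximum of 1
#' and are strictly positive.
#'
#' @param traj A `bstar_trajectory`.
#' @return Numeric vector of per-sample weights (`> 0`).
#' @export
radial_dcf <- function(traj) {
  r <- traj$radius
  dr <- traj$kmax / (traj$n_samp - 1)
  d <- traj$ndim
  w <- r^(d - 1)
  w[r < dr / 2] <- dr^(d - 1) / (2^d * d)
  w / max(w)
}

#' GIRF kernel
#'
#' Discrete impulse response of the gradient chain per axis (a linear,
#' time-invariant model). A distortion-free system has a unit-sum Dirac
#' kernel. The same kernel may be shared across axes (a single numeric
#' vector) or given per axis (a list of vectors).
#'
#' @param h Numeric vector (shared) or list of per-axis vectors.
#' @param dwell Sample spacing of the kernel (microseconds).
#' @param origin Index (1-based) of the kernel tap corresponding to zero
#'   delay; `h = 1` with `origin = 1` is the identity.
#' @return A `girf_kernel` object.
#' @export
girf_kernel <- function(h, dwell = 1, origin = 1) {
  hs <- if (is.list(h)) h else list(h)
  if (any(vapply(hs, length, 1L) == 0)) stop("empty GIRF kernel")
  if (dwell <= 0) stop("dwell must be positive")
  structure(list(h = h, dwell = dwell, origin = as.integer(origin)),
            class = "girf_kernel")
}

#' Apply a GIRF correction to a trajectory
#'
#' Models the gradient chain as a per-axis linear system: the nominal
#' gradient waveform of every half-projection (finite differences of the
#' time-ordered k-space positions at the gradient raster) is convolved
#' with the impulse-response kernel and re-integrated from the
#' half-projection's initial k-space position. The identity kernel is an
#' exact no-op; sample count is unchanged.
#'
#' @param traj A `bstar_trajectory`.
#' @param kernel A [girf_kernel()].
#' @return A corrected `bstar_trajectory` (dcf recomputed from the
#'   corrected radii).
#' @export
apply_girf <- function(traj, kernel) {
  if (!inherits(kernel, "girf_kernel")) stop("kernel must be a girf_kernel")
  hs <- if (is.list(kernel$h)) kernel$h else
    rep(list(kernel$h), traj$ndim)
  if (length(hs) != traj$ndim)
    stop("kernel must have one impulse response per axis (or be shared)")
  ns <- traj$n_samp
  out <- traj$coords
  for (ax in seq_len(traj$ndim)) {
    h <- hs[[ax]]
    k <- matrix(traj$coords[, ax], nrow = ns)  # time order per half-proj
    g <- apply(k, 2, diff)                     # (ns-1) x n_half gradients
    gc_ <- apply(g, 2, function(gi) {
      full <- stats::convolve(gi, rev(h), type = "open")
      full[kernel$origin:(kernel$origin + length(gi) - 1)]
    })
    kint <- apply(matrix(gc_, nrow = ns - 1), 2, cumsum)
    kc <- rbind(k[1, ], sweep(matrix(kint, nrow = ns - 1), 2, k[1, ], `+`))
    out[, ax] <- as.vector(kc)
  }
  traj$coords <- out
  traj$radius <- sqrt(rowSums(out^2))
  traj$dcf <- radial_dcf(traj)
  traj
}

#' Total acquisition time
#'
#' One center-out/center-in spoke pair is acquired per TR, so the scan
#' time is simply `n_spokes * TR`.
#'
#' @param n_spokes Number of spokes (TRs), `>= 0`.
#' @param TR Repetition time (ms).
#' @return Acquisition time in seconds.
#' @examples
#' acquisition_time(40000, 4.52)  # 180.8 s ~ 3:01
#' @export
acquisition_time <- function(n_spokes, TR) {
  if (any(n_spokes < 0)) stop("n_spokes must be non-negative")
  if (any(TR <= 0)) stop("TR must be positive")
  n_spokes * TR * 1e-3
}

#' Undersampling factor of a half-radial protocol
#'
#' Ratio of the number of half-projections required for Nyquist sampling
#' of the sphere surface to the number acquired. Under the default
#' `"sphere_nyquist"` convention `R = pi M^2 / N_half` with
#' `M = FOV/resolution` and `N_half = 2 n_spokes`. The convention label
#' is always attached to the result, since published undersampling
#' factors depend on the (often unstated) convention.
#'
#' @param protocol A [protocol_params()] object.
#' @param convention Convention label; only `"sphere_nyquist"` is defined.
#' @return Dimensionless R with attribute `convention`.
#' @export
undersampling_factor <- function(protocol, convention = "sphere_nyquist") {
  if (!identical(convention, "sphere_nyquist"))
    stop("unknown undersampling-factor convention: ", convention)
  M <- protocol$fov_mm / protocol$resolution_mm
  R <- pi * M^2 / (2 * protocol$n_spokes)
  structure(R, convention = convention)
}

#' Write / read a trajectory as a delimited text table
#'
#' Columns: `half_projection`, `sample`, `kx`, `ky` (, `kz`), `dcf`,
#' `echo`; suitable for exchange with external reconstruction tools.
#'
#' @param traj A `bstar_trajectory`.
#' @param path Output file path (TSV).
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `bstar_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  ax <- c("kx", "ky", "kz")[seq_len(traj$ndim)]
  df <- data.frame(
    half_projection = rep(seq_len(traj$n_half), each = traj$n_samp),
    sample = rep(seq_len(traj$n_samp), traj$n_half))
  for (i in seq_len(traj$ndim)) df[[ax[i]]] <- traj$coords[, i]
  df$dcf <- traj$dcf
  df$echo <- rep(traj$echo, each = traj$n_samp)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param kmax Nominal maximum radius (cycles/mm); recomputed from the
#'   table if omitted.
#' @export
read_trajectory <- function(path, kmax = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  ax <- intersect(c("kx", "ky", "kz"), names(df))
  n_samp <- max(df$sample)
  n_half <- max(df$half_projection)
  coords <- as.matrix(df[order(df$half_projection, df$sample), ax])
  dimnames(coords) <- NULL
  structure(list(
    coords = coords,
    echo = as.integer(df$echo[df$sample == 1][order(df$half_projection[df$sample == 1])]),
    radius = sqrt(rowSums(coords^2)),
    kmax = kmax %||% max(sqrt(rowSums(coords^2))),
    n_half = as.integer(n_half), n_samp = as.integer(n_samp),
    ndim = length(ax),
    dcf = df$dcf[order(df$half_projection, df$sample)]
  ), class = "bstar_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
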