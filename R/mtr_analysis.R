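#' Magnetization transfer ratio map
#'
#' `MTR = 100 (S - S_MT) / S` per voxel, in percent units (pu), from
#' co-registered-by-construction magnitude volumes (no registration is
#' performed). Voxels with `S <= 0` inside the mask are excluded (their
#' count is recorded); reported values are clipped to `[-50, 150]` pu
#' with the out-of-range fraction recorded.
#'
#' @param s Non-MT-weighted magnitude volume (array or `image_volume`).
#' @param s_mt MT-weighted magnitude volume.
#' @param mask Logical array of brain/object voxels; default: all.
#' @return An `mtr_map` object: list with `mtr` (array, pu, `NA` outside
#'   the mask), `mask`, `n_excluded`, `frac_out_of_range`, `provenance`.
#' @export
compute_mtr <- function(s, s_mt, mask = NULL) {
  prov <- list(
    non_mt = if (inherits(s, "image_volume")) s$provenance else NULL,
    mt = if (inherits(s_mt, "image_volume")) s_mt$provenance else NULL)
  if (inherits(s, "image_volume")) s <- s$data
  if (inherits(s_mt, "image_volume")) s_mt <- s_mt$data
  s <- Mod(s); s_mt <- Mod(s_mt)
  if (!all(dim(s) == dim(s_mt))) stop("volumes must share the same grid")
  if (is.null(mask)) mask <- array(TRUE, dim(s))
  bad <- mask & s <= 0
  n_excluded <- sum(bad)
  if (n_excluded > 0)
    message(n_excluded, " voxels with S <= 0 excluded from the MTR mask")
  use <- mask & !bad
  mtr <- array(NA_real_, dim(s))
  mtr[use] <- 100 * (s[use] - s_mt[use]) / s[use]
  oob <- sum(mtr[use] < -50 | mtr[use] > 150) / max(sum(use), 1)
  mtr[use] <- pmin(pmax(mtr[use], -50), 150)
  structure(list(mtr = mtr, mask = use, n_excluded = n_excluded,
                 frac_out_of_range = oob, provenance = prov),
            class = "mtr_map")
}

#' @export
print.mtr_map <- function(x, ...) {
  cat(sprintf("mtr_map: %s voxels, %d in mask, median %.1f pu\n",
              paste(dim(x$mtr), collapse = "x"), sum(x$mask),
              stats::median(x$mtr[x$mask])))
  invisible(x)
}

#' Off-resonance map from a dual-echo acquisition
#'
#' `f = angle(vol2 conj(vol1)) / (2 pi dTE)`, unambiguous over
#' `+-1/(2 dTE)` (e.g. +-62.5 Hz at dTE = 8 ms); frequencies beyond
#' alias back into this range unless unwrapped.
#'
#' @param vol1,vol2 Complex volumes at the shorter/longer echo time.
#' @param dte Echo-time difference (ms), `> 0`.
#' @return Off-resonance map (Hz) with attribute `range_hz`.
#' @export
fieldmap_from_dual_echo <- function(vol1, vol2, dte) {
  if (inherits(vol1, "image_volume")) vol1 <- vol1$data
  if (inherits(vol2, "image_volume")) vol2 <- vol2$data
  if (dte <= 0) stop("dte must be positive")
  f <- Arg(vol2 * Conj(vol1)) / (2 * pi * dte * 1e-3)
  attr(f, "range_hz") <- 1 / (2 * dte * 1e-3)
  f
}

#' Fraction of masked voxels within an off-resonance bound
#'
#' @param fieldmap Off-resonance map (Hz).
#' @param mask Logical array (non-empty).
#' @param bound_hz Bound (Hz), `>= 0`.
#' @return Fraction in `[0, 1]`.
#' @export
offres_coverage <- function(fieldmap, mask, bound_hz) {
  if (sum(mask) == 0) stop("mask is empty")
  mean(abs(fieldmap[mask]) <= bound_hz)
}

#' MTR histogram and peak
#'
#' Histogram of the masked MTR values on bins of width `bin_width`
#' (default 1 pu); the peak is the center of the maximal bin, ties
#' broken toward lower MTR.
#'
#' @param map An `mtr_map` (or numeric array with `mask` supplied).
#' @param bin_width Bin width (pu), `> 0`.
#' @param mask Optional logical array when `map` is a bare array.
#' @return A `histogram_summary`: list with `bin_edges`, `counts`,
#'   `peak_pu`.
#' @export
mtr_histogram_peak <- function(map, bin_width = 1, mask = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  vals <- if (inherits(map, "mtr_map")) map$mtr[map$mask] else map[mask %||% TRUE]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no MTR values inside the mask")
  # bins centered on integer multiples of bin_width, so a constant map
  # at a multiple of the bin width peaks exactly there
  lo <- round(min(vals) / bin_width) * bin_width - bin_width / 2
  hi <- round(max(vals) / bin_width) * bin_width + bin_width / 2
  edges <- seq(lo, hi, by = bin_width)
  counts <- graphics::hist(vals, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  peak_bin <- which.max(counts)  # which.max takes the first (lowest) tie
  structure(list(bin_edges = edges, counts = counts,
                 peak_pu = edges[peak_bin] + bin_width / 2),
            class = "histogram_summary")
}

#' Scan-rescan repeatability summary of MTR histogram peaks
#'
#' Sample statistics (sd with n-1) of the histogram-peak positions
#' across repeated scans, as displayed in a box plot: mean, sd, median,
#' lower/upper quartile, min, max.
#'
#' @param peaks Numeric vector of peak positions (pu), length `>= 2`.
#' @return Named list of statistics (pu).
#' @export
repeatability_summary <- function(peaks) {
  if (length(peaks) < 2) stop("need at least 2 peak values")
  q <- stats::quantile(peaks, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(peaks), mean = mean(peaks), sd = stats::sd(peaks),
       median = q[2], lower_quartile = q[1], upper_quartile = q[3],
       min = min(peaks), max = max(peaks))
}

#' Apparent SNR from signal and noise regions of interest
#'
#' `mean(|image|) in the signal ROI / sd(|image|) in a noise-only ROI`;
#' no Rayleigh correction is applied, so values are comparable only
#' between images from the same reconstruction method.
#'
#' @param image Magnitude image (array; complex input is modded).
#' @param signal_roi,noise_roi Logical arrays (non-empty, disjoint).
#' @return Apparent SNR (dimensionless); `Inf` with a warning if the
#'   noise sd is zero.
#' @export
apparent_snr <- function(image, signal_roi, noise_roi) {
  if (inherits(image, "image_volume")) image <- image$data
  image <- Mod(image)
  if (sum(signal_roi) == 0 || sum(noise_roi) == 0)
    stop("both ROIs must be non-empty")
  if (any(signal_roi & noise_roi)) stop("ROIs must be disjoint")
  nsd <- stats::sd(image[noise_roi])
  if (nsd == 0) {
    warning("noise ROI has zero standard deviation; SNR is infinite")
    return(Inf)
  }
  mean(image[signal_roi]) / nsd
}
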