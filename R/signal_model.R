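#' Tissue parameter set
#'
#' Bundles the relaxation and proton-density parameters of one tissue
#' compartment, plus its true magnetization-transfer ratio and local
#' off-resonance, with validity checks.
#'
#' @param T1 Longitudinal relaxation time (ms), `> 0`.
#' @param T2 Transverse relaxation time (ms), `> 0` and `<= T1`.
#' @param PD Proton density relative to an aqueous phantom (0-1 scale).
#' @param mtr_true True magnetization-transfer ratio in percent units
#'   (pu), in `[0, 100]`.
#' @param off_res Local off-resonance (Hz).
#'
#' @return An object of class `tissue_params`.
#' @examples
#' wm <- tissue_params(T1 = 450, T2 = 90, PD = 0.7, mtr_true = 43.3)
#' @export
tissue_params <- function(T1, T2, PD = 1, mtr_true = 0, off_res = 0) {
  stopifnot(is.numeric(T1), is.numeric(T2), is.numeric(PD))
  if (any(T1 <= 0) || any(T2 <= 0))
    stop("relaxation times T1 and T2 must be positive")
  if (any(T2 > T1))
    stop("T2 must not exceed T1")
  if (any(PD < 0))
    stop("PD must be non-negative")
  if (any(mtr_true < 0) || any(mtr_true > 100))
    stop("mtr_true must lie in [0, 100] percent units")
  structure(list(T1 = T1, T2 = T2, PD = PD,
                 mtr_true = mtr_true, off_res = off_res),
            class = "tissue_params")
}

#' Sequence timing parameters
#'
#' @param TR Repetition time (ms).
#' @param TE1 First echo time (ms), `0 < TE1 < TE2 < TR`.
#' @param TE2 Second echo time (ms).
#' @param alpha Flip angle (degrees), in `(0, 180)`.
#' @param TRF RF pulse duration (microseconds), `> 0`.
#'
#' @return An object of class `sequence_timing`.
#' @export
sequence_timing <- function(TR, TE1 = TR / 2, TE2 = NULL, alpha = 40,
                            TRF = 600) {
  if (is.null(TE2)) TE2 <- TE1
  if (!(TR > 0)) stop("TR must be positive")
  if (!(TE1 > 0 && TE1 <= TE2 && TE2 < TR))
    stop("echo times must satisfy 0 < TE1 <= TE2 < TR")
  if (!(alpha > 0 && alpha < 180))
    stop("flip angle must lie in (0, 180) degrees")
  if (!(TRF > 0)) stop("TRF must be positive")
  structure(list(TR = TR, TE1 = TE1, TE2 = TE2, alpha = alpha, TRF = TRF),
            class = "sequence_timing")
}

#' Balanced SSFP steady-state signal
#'
#' Complex transverse steady-state magnetization of an alternating-RF
#' (phase-cycled) bSSFP sequence, as a fraction of M0, for a tissue at a
#' given off-resonance. The alternating-RF convention places the passband
#' center on resonance and the banding nulls at `+-1/(2 TR)`. The
#' signal is evaluated at echo time `TE` including `exp(-TE/T2)` decay and
#' free-precession phase `2*pi*f*TE`.
#'
#' With `E1 = exp(-TR/T1)`, `E2 = exp(-TR/T2)` and per-TR precession
#' `theta = 2*pi*f*TR + pi` (the `+pi` encodes RF phase alternation), the
#' post-pulse steady state is
#' `M0 PD (1-E1) sin(a) (1 - E2 exp(i theta)) / ((1-E1 cos a)(1-E2 cos theta)
#'  - E2 (E1-cos a)(E2-cos theta))`.
#' On resonance this reduces to the familiar passband magnitude
#' `PD sin(a) (1-E1) / (1-(E1-E2)cos a - E1 E2)`.
#'
#' All tissue arguments may be vectors/arrays (recycled), so whole
#' parameter grids can be evaluated in one call.
#'
#' @param tissue A [tissue_params()] object, or a list with numeric
#'   (possibly array) fields `T1`, `T2`, `PD`.
#' @param timing A [sequence_timing()] object (uses `TR`, `TE1`, `alpha`).
#' @param off_res_hz Off-resonance frequency (Hz); vector/array allowed.
#' @param TE Echo time at which the signal is observed (ms); defaults to
#'   `timing$TE1`.
#'
#' @return Complex signal (same shape as the broadcast inputs), in units
#'   of M0.
#' @examples
#' wm <- tissue_params(450, 90, 0.7)
#' tm <- sequence_timing(TR = 4.52, TE1 = 0.93, TE2 = 3.51, alpha = 40)
#' Mod(bssfp_signal(wm, tm, off_res_hz = 0))
#' @export
bssfp_signal <- function(tissue, timing, off_res_hz = 0, TE = timing$TE1) {
  if (any(tissue$T1 <= 0) || any(tissue$T2 <= 0))
    stop("relaxation times must be positive")
  TR <- timing$TR
  a <- timing$alpha * pi / 180
  E1 <- exp(-TR / tissue$T1)
  E2 <- exp(-TR / tissue$T2)
  theta <- 2 * pi * off_res_hz * TR * 1e-3 + pi
  num <- (1 - E1) * sin(a) * (1 - E2 * exp(1i * theta))
  den <- (1 - E1 * cos(a)) * (1 - E2 * cos(theta)) -
    E2 * (E1 - cos(a)) * (E2 - cos(theta))
  m <- tissue$PD * num / den
  m * exp(-TE / tissue$T2) * exp(1i * 2 * pi * off_res_hz * TE * 1e-3)
}

#' On-resonant bSSFP signal in the TR -> 0 limit
#'
#' Closed-form short-TR limit of the on-resonant passband signal,
#' `PD sin(a) / ((T1/T2)(1 - cos a) + (1 + cos a))`. In this regime the
#' signal (and hence flip-angle matching) is insensitive to the exact TR.
#'
#' @param tissue A [tissue_params()] object (uses `T1`, `T2`, `PD`).
#' @param alpha_deg Flip angle (degrees); vectorized.
#' @return Signal magnitude in units of M0 (no echo-time decay).
#' @export
bssfp_signal_tr0 <- function(tissue, alpha_deg) {
  a <- alpha_deg * pi / 180
  tissue$PD * sin(a) /
    ((tissue$T1 / tissue$T2) * (1 - cos(a)) + (1 + cos(a)))
}

#' Banding (stopband null) frequency of bSSFP
#'
#' For alternating-RF bSSFP the signal nulls sit at off-resonances of
#' `+-1/(2 TR)`; at TR = 4.52 ms this is about +-110 Hz.
#'
#' @param TR Repetition time (ms).
#' @return Banding frequency (Hz).
#' @export
banding_frequency <- function(TR) {
  if (any(TR <= 0)) stop("TR must be positive")
  1 / (2 * TR * 1e-3)
}

#' Passband half-width of bSSFP
#'
#' The flat central portion of the bSSFP frequency response, taken as
#' `+-1/(3 TR)` (about +-74 Hz at TR = 4.52 ms); always 2/3 of the
#' banding frequency.
#'
#' @param TR Repetition time (ms).
#' @return Passband half-width (Hz).
#' @export
passband_halfwidth <- function(TR) {
  if (any(TR <= 0)) stop("TR must be positive")
  1 / (3 * TR * 1e-3)
}

#' Match the phantom flip angle to a reference tissue signal
#'
#' Solves `PD_p * Mxy(T1_p, T2_p, alpha) = PD_r * Mxy(T1_r, T2_r,
#' alpha_ref)` for `alpha` on `[0, alpha_ref]`, using the TR -> 0 limit of
#' the on-resonant bSSFP signal (flip-angle matching is marginally
#' dependent on TR for TR << T2). Used to lower the flip angle of an
#' aqueous phantom scan (high T2/T1, high PD) so its signal matches brain
#' white matter.
#'
#' @param phantom [tissue_params()] of the phantom to be matched.
#' @param reference [tissue_params()] of the reference tissue.
#' @param alpha_ref Reference flip angle (degrees).
#' @param tol Relative residual tolerance of the root (default 1e-9).
#' @return Matched flip angle in degrees (unrounded).
#' @examples
#' ph <- tissue_params(150, 100, 1.0)
#' wm <- tissue_params(450, 90, 0.7)
#' round(match_flip_angle(ph, wm, 40))  # 18
#' @export
match_flip_angle <- function(phantom, reference, alpha_ref, tol = 1e-9) {
  target <- bssfp_signal_tr0(reference, alpha_ref)
  f <- function(a) bssfp_signal_tr0(phantom, a) - target
  lo <- 1e-6
  if (f(lo) * f(alpha_ref) > 0) {
    # no sign change: either unreachable, or the response is non-monotone
    # over [0, alpha_ref]; scan for an interior bracket before giving up
    grid <- seq(lo, alpha_ref, length.out = 512)
    fg <- vapply(grid, f, numeric(1))
    idx <- which(fg[-1] * fg[-length(fg)] <= 0)
    if (length(idx) == 0)
      stop("no flip angle in [0, alpha_ref] matches the reference signal")
    lo <- grid[idx[1]]
    alpha_ref_hi <- grid[idx[1] + 1]
  } else {
    alpha_ref_hi <- alpha_ref
  }
  root <- stats::uniroot(f, c(lo, alpha_ref_hi), tol = 1e-12)$root
  # Newton polish
  for (i in 1:4) {
    h <- 1e-6
    d <- (f(root + h) - f(root - h)) / (2 * h)
    if (abs(d) < .Machine$double.eps) break
    root <- root - f(root) / d
    root <- min(max(root, 0), alpha_ref)
  }
  if (abs(f(root)) > tol * abs(target))
    stop("flip-angle matching did not converge to the requested residual")
  root
}

#' Apply phenomenological MT weighting to a signal
#'
#' Scales a non-MT-weighted signal by `(1 - mtr_true/100)`, the
#' per-voxel depletion that defines the true magnetization-transfer
#' ratio; the exact inverse of [compute_mtr()] by construction.
#'
#' @param s_non_mt Non-MT-weighted signal (numeric or complex, any shape).
#' @param mtr_true True MTR in percent units, in `[0, 100]`; recycled.
#' @return MT-weighted signal, same shape as `s_non_mt`.
#' @export
mt_weighted_signal <- function(s_non_mt, mtr_true) {
  if (any(mtr_true < 0) || any(mtr_true > 100))
    stop("mtr_true must lie in [0, 100] percent units")
  s_non_mt * (1 - mtr_true / 100)
}

#' Ideally spoiled gradient-echo (SPGR) steady-state signal
#'
#' `PD sin(a) (1-E1) / (1 - E1 cos a) * exp(-TE/T2) * exp(i 2 pi f TE)`,
#' with T2* modeled as T2 (no mesoscopic dephasing). Used by the
#' dual-echo B0-mapping simulator, where the phase at the echo is exactly
#' `2 pi f TE`.
#'
#' @param tissue A [tissue_params()] object or list of arrays.
#' @param TR Repetition time (ms).
#' @param TE Echo time (ms).
#' @param alpha Flip angle (degrees).
#' @param off_res_hz Off-resonance (Hz); vector/array allowed.
#' @return Complex signal in units of M0.
#' @export
spgr_signal <- function(tissue, TR, TE, alpha, off_res_hz = 0) {
  if (any(tissue$T1 <= 0) || any(tissue$T2 <= 0))
    stop("relaxation times must be positive")
  if (TR <= 0 || TE < 0) stop("TR must be positive and TE non-negative")
  a <- alpha * pi / 180
  E1 <- exp(-TR / tissue$T1)
  tissue$PD * sin(a) * (1 - E1) / (1 - E1 * cos(a)) *
    exp(-TE / tissue$T2) * exp(1i * 2 * pi * off_res_hz * TE * 1e-3)
}

#' Voxel-volume SNR penalty between two isotropic resolutions
#'
#' Ratio of voxel volumes `(res_fine / res_coarse)^3`: the theoretical
#' SNR penalty paid when moving from `res_coarse` to `res_fine` isotropic
#' voxels (about 0.5 for 0.69 mm vs 0.87 mm).
#'
#' @param res_fine Finer isotropic resolution (mm).
#' @param res_coarse Coarser isotropic resolution (mm).
#' @return Dimensionless penalty factor in (0, 1] when `res_fine <=
#'   res_coarse`.
#' @export
voxel_snr_penalty <- function(res_fine, res_coarse) {
  if (res_fine <= 0 || res_coarse <= 0) stop("resolutions must be positive")
  (res_fine / res_coarse)^3
}
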