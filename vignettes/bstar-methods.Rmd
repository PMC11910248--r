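---
title: "Models and methods behind bstarsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bstarsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bstarsim` is a desk-scale simulator and reconstruction toolkit for
half-radial dual-echo balanced SSFP (bSTAR) brain MRI at low field, with
an analysis layer for magnetization transfer ratio (MTR) mapping. This
vignette explains the models it implements, the parameters that matter,
the numerical choices, and what the synthetic experiments do and do not
demonstrate.

## The bSSFP steady state and its frequency response

The signal model is the standard alternating-RF balanced SSFP steady
state. With $E_1 = e^{-TR/T_1}$, $E_2 = e^{-TR/T_2}$, flip angle
$\alpha$ and per-TR precession $\theta = 2\pi f\,TR + \pi$ (the $+\pi$
encodes RF phase alternation, placing the passband center on
resonance), `bssfp_signal()` evaluates

$$M_{xy} = PD\,\frac{(1-E_1)\sin\alpha\,(1 - E_2 e^{i\theta})}
{(1-E_1\cos\alpha)(1-E_2\cos\theta) - E_2(E_1-\cos\alpha)(E_2-\cos\theta)}
\cdot e^{-TE/T_2}\, e^{i 2\pi f\,TE}.$$

Its magnitude is $1/TR$-periodic and even in the off-resonance $f$,
with signal nulls (banding) at $\pm 1/(2TR)$ — about $\pm 110$ Hz at
$TR = 4.52$ ms — and a flat passband conventionally taken as
$\pm 1/(3TR)$, about $\pm 74$ Hz. At low field, where brain
off-resonance rarely exceeds $\pm 50$ Hz, any $TR \lesssim 5$ ms keeps
the whole brain inside the passband; this is the regime the package's
brain simulations operate in.

On resonance and for $TR \ll T_2$ the signal tends to the closed form

$$M_{xy} \to \frac{PD\,\sin\alpha}{(T_1/T_2)(1-\cos\alpha) +
(1+\cos\alpha)},$$

implemented as `bssfp_signal_tr0()`. `match_flip_angle()` solves
$PD_p M(T_{1,p}, T_{2,p}, \alpha) = PD_r M(T_{1,r}, T_{2,r},
\alpha_{ref})$ for $\alpha$ in this limit — the flip-angle setting is
only marginally TR-dependent there — using bracketing root finding
(`uniroot`) with a short Newton polish, and verifies the residual to
$10^{-9}$ relative. For an aqueous phantom ($T_1/T_2 = 150/100$ ms,
$PD = 1$) matched to white matter ($450/90$ ms, $PD = 0.7$) at
$\alpha_{ref} = 40^\circ$ this yields $18^\circ$ to the nearest degree.

Magnetization transfer is modeled phenomenologically: an MT-weighted
acquisition multiplies each voxel's signal by $(1 - MTR_{true}/100)$
(`mt_weighted_signal()`). A two-pool Bloch–McConnell model is out of
scope; the physical mechanism (RF pulse duration modulating saturation
of the macromolecular pool) enters only through the protocol presets'
$T_{RF}$ values. The consequence is that the pipeline tests recovery of
an injected depletion, not MT physics itself. Because the MT and non-MT
protocols differ in TR and echo times, their steady-state amplitudes
differ slightly; numerically the TR and TE effects nearly cancel for
white matter (ratio $\approx 1.000$), so the injected MTR is recovered
without bias at the model level.

The SPGR signal used for B0 mapping assumes ideal spoiling,
$PD\sin\alpha\,(1-E_1)/(1-E_1\cos\alpha)\,e^{-TE/T_2}e^{i2\pi f TE}$,
with $T_2^*$ modeled as $T_2$: the quantity under test is the phase
evolution (field-map accuracy), not $T_2^*$ contrast.

## Trajectory

Each TR of the bSTAR acquisition samples one center-out and one
center-in half-projection of a bipolar readout. Directions follow a
generalized-spiral (Archimedean) construction on the sphere: heights
$z_i$ uniform in $(-1, 1)$ and azimuth increments
$\Delta\phi_i = \sqrt{n\pi}/\sqrt{n(1-z_i^2)}$, giving near-uniform
areal density. The center-out half-projection of spoke $i$ takes spiral
direction $2i-1$ and its center-in partner direction $2i$, so the two
echoes interleave over the sphere. Samples are uniform in radius up to
$k_{max} = 1/(2\,\Delta x)$; center-in half-projections are stored in
time order (edge to center). Density compensation is the analytic
radial weight $w \propto r^{d-1}$ — exact for ideal radial sampling and
far cheaper than Voronoi weights — with a flat floor below half a
radial step whose value is the exact center-cell volume fraction
$\Delta r^{d-1}/(2^d d)$: the $k = 0$ sample is re-acquired by every
half-projection, so its Voronoi cell is the small disc (2D) or sphere
(3D) of radius $\Delta r/2$ split among them, 1/8 or 1/24 of the first
ring's per-sample weight. Capping the floor at the first ring's weight
instead overweights the duplicated DC samples and shows up as a
near-constant background offset comparable to tissue signal in the
adjoint reconstruction.

GIRF correction treats the gradient chain as a per-axis linear
time-invariant system: nominal gradient waveforms (finite differences
of k along each half-projection) are convolved with a measured impulse
response and re-integrated. The undersampling factor is reported under
an explicit convention, $R = \pi M^2 / N_{half}$ with $M =
FOV/\Delta x$ (half-projections needed for sphere-surface Nyquist over
acquired); published tables often use other, unstated conventions, so
the label travels with the number.

## Digital phantoms

`make_resolution_phantom()` builds an ACR-like disc of aqueous tissue
($T_1 = 150$ ms, $T_2 = 100$ ms) with a signal-free insert drilled by
3×3 lattices of water-filled rods (defaults 0.9/0.8/0.7 mm, spacing
twice the diameter — the lattice spacing is a documented choice, as is
the insert layout). `make_brain_phantom()` nests ellipsoids: CSF shell,
gray-matter shell, white-matter core, two CSF ventricles. White matter
carries $T_1/T_2 = 450/90$ ms, $PD = 0.7$ and $MTR_{true} = 43.3$ pu;
the GM (650/100 ms, 0.8, 38 pu) and CSF (3500/1500 ms, 1.0, 2 pu)
values are literature-plausible fixed defaults — the analysis never
depends on their exact values, only on recovering whatever was
injected. Rasterization supersamples 4× per axis; partial volumes mix
in proton density (signal space), not in relaxation times.

The off-resonance generator blends a seeded low-order harmonic bulk
field bounded by $\pm 50$ Hz with one localized Gaussian hotspot
(default peak 80 Hz, near the anterior-inferior margin, emulating the
susceptibility focus above the nasal cavity); with the defaults, at
least 99% of voxels stay within $\pm 50$ Hz. Coil maps come from
virtual elements on a ring with broad Gaussian profiles and smooth
seeded phases, normalized to root-sum-of-squares ≈ 1 over the central
object region; all generators are pure functions of their parameters
and seed.

## Forward simulation

`simulate_bstar()` evaluates the per-voxel steady state at the echo
time of each half-projection's $k = 0$ crossing ($TE_1$ center-out,
$TE_2$ center-in), applies coil weighting, and maps to the non-uniform
samples with the gridding NUFFT. Off-resonance phase along the readout
uses $t = TE \pm (r/k_{max})\,T_{half}$, where the half-readout
duration $T_{half}$ is derived from samples per half-projection,
bandwidth per pixel and matrix size; the voxel-dependent factor
$e^{i2\pi f (t - TE)}$ is applied by linear time segmentation with an
interpolation node pinned at $t = TE$, so the echo crossing is exact
(with $|f| \le 80$ Hz and $T_{half} \approx 0.9$ ms the segmentation
error is negligible at 6 nodes). Noise is i.i.d. circular complex
Gaussian per coil sample, drawn from a local seeded stream so
simulations are bit-reproducible and never disturb the caller's RNG.

The NUFFT itself is a Kaiser–Bessel gridding transform on a
2×-oversampled FFT grid with a Beatty-style shape parameter. The
interpolation is materialized once per trajectory as a sparse matrix,
which makes the adjoint its exact transpose (the inner-product identity
holds to machine precision by construction) and lets one plan serve all
coils, echoes and iterations. Absolute accuracy against the exact
non-uniform DFT is set by the kernel width: ~$10^{-4}$ at width 4,
~$10^{-7}$ at width 8. The simulator defaults to width 8; the
iterative reconstruction defaults to width 5, where kernel error is
far below the data misfit it iterates on.

## Reconstruction

`adjoint_recon()` is the density-compensated gridding baseline,
combined across coils with conjugate sensitivities.
`estimate_coil_sensitivities()` forms low-resolution per-coil images
from a Hann-windowed central k-space disc and divides by their
root-sum-of-squares; maps estimated on the non-MT scan are reused for
the MT-weighted reconstruction so no intensity bias enters the MTR
(the package tests that this reuse changes the MT reconstruction by
< 2% RMS relative to self-calibration).

`fista_recon()` minimizes
$\tfrac12\|\sqrt{D}(Ax - y)\|^2 + \lambda\|Wx\|_1$, with $A$ the
coil-weighted NUFFT of one echo, $D$ the radial density-compensation
weights and $W$ an orthonormal periodic Daubechies-4 wavelet
(implemented in-package; 3 levels by default, capped so every block
stays even). Choices worth stating:

* **Density weighting in the data term.** Preconditioning by $D$ is
  what makes a 12-iteration budget meaningful for radial data; without
  it the normal operator is badly conditioned and FISTA at 12
  iterations is visibly unconverged.
* **$\lambda$ normalization.** The published weight 0.05 is interpreted
  relative to the maximum magnitude of the initial (adjoint) image.
  This makes the reconstruction exactly equivariant under global
  scaling of the data, a property the tests assert. The normalization
  convention of the original reconstruction is unstated, so this is a
  documented package convention, configurable via `recon_config()`.
* **Monotone FISTA.** The monotone variant keeps the best iterate, so
  the objective sequence is non-increasing by construction and can be
  asserted rather than merely hoped for.
* **Initialization.** The adjoint image scaled by its optimal
  least-squares amplitude $\arg\min_a \|\sqrt{D}(A(a\,x_{adj})-y)\|$;
  the Lipschitz constant comes from power iteration on $A^H D A$
  started from the adjoint image (deterministic), with an explicit
  error if it fails to settle.
* **Per-echo reconstruction.** The two echoes are reconstructed
  independently and added in complex space (`combine_echoes()`); an
  inter-echo phase of $\pi$ — off-resonance $1/(2(TE_2-TE_1))$ —
  cancels destructively, which the tests construct explicitly.

Full-size matrices (384³/512³) are supported by the same code path,
but the shipped tests and experiments run 2D analogs and volumes up to
64³; the methods are dimension-agnostic.

## MTR and B0 analysis

`compute_mtr()` implements $MTR = 100\,(S - S_{MT})/S$ in percent
units on magnitude images, with no registration step (the simulated
pairs are co-registered by construction). Voxels with $S \le 0$ inside
the mask are excluded and counted; reported values are clipped to
$[-50, 150]$ pu with the out-of-range fraction recorded. The histogram
peak uses 1-pu bins (a documented default) centered on integer
multiples of the bin width, peak = center of the maximal bin, ties
toward lower MTR. `fieldmap_from_dual_echo()` computes
$f = \arg(v_2 \bar v_1)/(2\pi\,\Delta TE)$, unambiguous over
$\pm 1/(2\Delta TE)$ ($\pm 62.5$ Hz at $\Delta TE = 8$ ms — note an
80 Hz focus aliases to $-45$ Hz unless unwrapped; the wrap range is
always attached to the result). Apparent SNR is mean magnitude over a
signal ROI divided by the magnitude standard deviation of a noise-only
ROI, with no Rayleigh correction — comparable only within one
reconstruction method.

## Study conditions of the synthetic experiments

The experiments in `run_experiment()` fix the conditions under which
the package's claims are tested:

* **Geometry.** 2D analogs at 192 mm FOV; matrix 160 for the
  resolution phantom (0.25 mm voxels around 0.9/0.8/0.7 mm rods), 96
  for the single MTR pipeline, 128 for scan–rescan (enough white-matter
  voxels for a stable 1-pu histogram mode). A 2D radial acquisition
  streaks far more than a 3D half-radial one at the same undersampling
  factor, so the MTR experiments use an in-plane $R = 3$ as the analog
  of the published volumetric $R = 8$, while the rod-resolution
  experiment deliberately keeps the harsher in-plane $R = 8$ to probe
  resolution under HR-like undersampling. The phantom scan uses the
  matched (lowered) flip angle from `match_flip_angle()`, as the
  physical phantom scan did.
* **Noise operating point (SNR ≈ 20).** The apparent SNR of published
  reconstructions is measured on the final images, and for MT-weighted
  scans sits near 20. `mtr_noise_calibration()` therefore targets
  white-matter apparent SNR ≈ 20 in the FISTA-reconstructed,
  echo-combined MT-weighted image: a first estimate from the linear
  adjoint noise gain (`calibrate_noise_sd()`, one noise-only adjoint
  reconstruction, exploiting linearity) is refined by one
  repeat-difference measurement through the actual nonlinear pipeline.
  The non-MT scan, acquired at the same k-space noise level, then sits
  near SNR 35–40, mirroring the published ordering.
* **Repeats.** Scan–rescan simulates 12 independent MT/non-MT pairs
  (fresh noise per repeat, coil maps re-estimated from each non-MT
  scan and reused for its MT partner) and summarizes the 12 histogram
  peaks by mean, sd, median, quartiles and extremes.

What passing these experiments shows: the chain
simulate → reconstruct → analyze recovers an injected MTR to within
±2 pu at realistic noise, with scan–rescan peak scatter below 1 pu, and
resolves 0.9 mm rods at HR-like undersampling. What it does not show:
anatomical realism (ellipsoid geometry, three tissues), MT physics
(phenomenological depletion), eddy-current or motion effects, or
in-vivo values — in-vivo SNR tables and off-resonance statistics are
reproduced as procedures, not as numeric targets.

## Degenerate inputs and tie-breaks

Non-positive relaxation times, invalid echo ordering, empty rod lists,
empty masks, zero-signal calibration regions, mismatched grids and
unknown presets/conventions all raise explicit errors. Histogram ties
break toward lower MTR; zero noise sd in an SNR ROI returns an
infinite-SNR sentinel with a warning; multi-coil reconstruction
without maps falls back to root-sum-of-squares with a warning.

## Known limitations

The NUFFT stores a sparse interpolation matrix per trajectory — memory
scales with samples × kernel volume, which is fine at desk scale but
would want a matrix-free kernel for 512³ work. The GIRF model is
linear and per-axis (no cross-terms, no B0 eddy terms). Spatial phase
unwrapping of field maps beyond the $\pm 1/(2\Delta TE)$ range is not
implemented; the range is reported instead. The scan-time and
undersampling calculators reproduce the printed protocol arithmetic
only to the extent the conventions are stated.
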