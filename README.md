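# bstarsim

Simulation, reconstruction and MTR analysis for half-radial dual-echo
balanced SSFP (bSTAR) brain MRI at low field.

## The problem

Balanced steady-state free precession (bSSFP) delivers high SNR
efficiency but suffers banding artifacts where the off-resonance phase
per TR approaches ±π. At 0.55 T, brain off-resonance rarely exceeds
±50 Hz, so a bSSFP acquisition with TR ≲ 5 ms keeps the whole brain
inside the flat passband (±1/(3·TR) ≈ ±74 Hz at TR = 4.52 ms, with
banding nulls at ±1/(2·TR) ≈ ±110 Hz) — opening the door to
sub-millimeter isotropic brain imaging and, by modulating the RF pulse
duration between two scans, to whole-brain magnetization transfer
ratio (MTR) mapping

    MTR = 100 · (S − S_MT) / S   [pu],

without separate saturation pulses. bSTAR samples one center-out and
one center-in radial half-projection per TR along an Archimedean
spiral on the sphere, reconstructed per echo by wavelet-regularized
FISTA compressed sensing and combined in complex space.

`bstarsim` re-implements this computational chain as a desk-scale
toolkit for people developing or validating non-Cartesian
reconstruction and MTR analysis: closed-form bSSFP/SPGR signal models,
flip-angle matching between phantom and tissue, trajectory design with
GIRF correction and analytic density compensation, seeded digital
phantoms (resolution rods, brain-like with MTR ground truth, smooth
off-resonance fields, synthetic coil maps), a gridding-NUFFT forward
simulator, adjoint and FISTA reconstruction with coil-sensitivity
estimation and reuse, and MTR / B0 / repeatability / apparent-SNR
analysis. No scanner data are required; everything runs on synthetic
phantoms.

## Worked example

Flip-angle matching: an aqueous phantom (T1/T2 = 150/100 ms, PD = 1)
scanned so its signal matches brain white matter (450/90 ms, PD = 0.7)
at a 40° reference:

```r
library(bstarsim)
aqueous <- tissue_params(150, 100, 1.0)
wm      <- tissue_params(450,  90, 0.7)
match_flip_angle(aqueous, wm, alpha_ref = 40)
#> [1] 18.0778
banding_frequency(4.52); passband_halfwidth(4.52)
#> [1] 110.6195
#> [1] 73.74631
```

So the phantom scan runs at 18° (nearest degree), and at the non-MT
protocol's TR = 4.52 ms banding sits at ±110.6 Hz with a ±73.7 Hz
passband.

An end-to-end MTR experiment — 2D brain phantom, MT / non-MT pair
simulated at white-matter apparent SNR ≈ 20, FISTA-reconstructed,
MTR histogram analyzed:

```r
m <- run_experiment("mtr_brain", seed = 1, matrix_n = 96,
                    out_dir = "exp_mtr")
m$wm_median_mtr_pu     # 43.0  (injected truth: 43.3 pu)
m$histogram_peaks_pu   # 43    (whole-"brain" histogram peak, 1 pu bins)
```

The white-matter median recovers the injected 43.3 pu to well within
±2 pu through the full simulate → reconstruct → analyze chain. Other
experiments: `"resolution_phantom"` (0.9/0.8/0.7 mm rod modulation at
HR-like undersampling — with seed 1 the 0.9 mm rods show 61%
modulation, i.e. clearly resolved), `"scan_rescan"` (12 repeated MTR
pipelines; with seed 1 the 12 peaks have mean 43.1 pu and sd 0.67 pu at
SNR ≈ 20) and `"b0_map"`
(dual-echo SPGR field mapping; ±62.5 Hz unambiguous range at
ΔTE = 8 ms).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/bstar.R simulate --protocol hr_nonmt --matrix 96 --out sim
Rscript inst/cli/bstar.R recon --kspace sim --matrix 96 --fov-mm 192 --out vol
Rscript inst/cli/bstar.R experiment --name scan_rescan --seed 1 --out exp
```

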