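# mammoiq

Physical image-quality metrics for phantom-based quality assurance of
digital mammography (DM) and synthesized 2-D mammography (SM — a 2-D image
reconstructed from tomosynthesis projections). The package is aimed at
medical physicists and imaging researchers who characterize detector and
reconstruction performance from repeated phantom acquisitions, and at
methodologists who need a fully synthetic, ground-truthed test bed for
such pipelines.

## What it computes

Given a stack of `n` repeated, co-registered phantom images with pixel
pitch Δ (mm), the package implements five standard metric families:

- **SNR maps and nonuniformity.** Pixelwise mean and sample-SD maps over
  the repeats, their ratio SNR(x, y) = μ(x, y)/σ(x, y), block means
  PV̄ᵢ over non-overlapping tiles, and the nonuniformity index
  NUI = (max PV̄ᵢ − min PV̄ᵢ) / ((max PV̄ᵢ + min PV̄ᵢ)/2).
- **Noise power spectrum.** From difference ("noise") images of
  same-condition pairs, NPS(fx, fy) = (ΔxΔy)/(NxNy) · ⟨|DFT(ROIₙ)|²⟩ · ½,
  the ½ undoing the variance doubling of the subtraction; radial and
  axial 1-D profiles, per-bin anisotropy ratios NPS_x/NPS_r and
  NPS_y/NPS_r, and a Wilcoxon signed-rank test of their logs against 0.
- **Mass CNR.** CNR = (PV̄_signal − PV̄_background)/σ_background on a local
  ROI with the mass masked out (geometric disk mask with a 1.2× safety
  inflation, or Otsu), so reconstruction halo pixels stay out of the
  background statistics.
- **Slanted-edge MTF.** Per-line subpixel edge detection, edge angle by
  linear regression, a pooled subpixel-binned composite ESF, an
  error-function model fit ESF(x) = a + b·erf((x−x0)/(σ√2)), the analytic
  Gaussian LSF, its DFT normalized to f = 0, and the f50/f10 readout
  (frequencies where MTF = 0.5 and 0.1), up to the Nyquist frequency
  1/(2Δ).
- **Contrast-detail scoring.** A transparent 4-alternative forced-choice
  template observer on a 16 × 16 gold-disk grid (guess rate 25%),
  psychometric thresholding at the conventional 62.5% level, the CD curve,
  and IQF⁻¹ = 100 / Σᵢ₌₁¹⁶ Cᵢ·D_{i,min}.

A synthetic phantom generator (`gen_flat_stack`, `gen_edge_stack`,
`gen_mass_image`, `gen_cdmam_stack`) produces all required inputs with
known ground truth, including DM-like and SM-like preset acquisition
conditions (`mammo_preset`, `run_preset_analysis`).

## Worked example

Slanted-edge MTF of a synthetic edge with a 0.08 mm Gaussian system blur
at 0.05 mm pitch, 10 frames with noise:

```r
library(mammoiq)
edge <- gen_edge_stack(shape_px = c(256, 256), spacing_mm = 0.05,
                       angle_deg = 1.54, psf_sigma_mm = 0.08,
                       edge_contrast_adu = 100, background_adu = 500,
                       noise_sd_adu = 1, n_images = 10, seed = 1)
res <- mtf_analysis(edge$stack, scan_direction = "x")
print(res$mtf)
#> <mtf_curve> 103 samples to 9.92 cycles/mm; f50 = 2.34, f10 = 4.27 cycles/mm
print(res$fit)
#> <erf_fit> a = 550, b = 50 ADU, x0 = 0.0002141 mm, sigma = 0.08006 mm (rms resid 0.0654)
```

The fitted edge-spread width recovers the generating blur (0.08006 vs
0.08 mm), and f50 = 2.34 cycles/mm matches the closed form
√(ln 2/(2π²σ²)) = 2.342 for a Gaussian blur. SNR uniformity of a
flat-field stack with a 10% peak-to-valley gain gradient:

```r
flat <- gen_flat_stack(shape_px = c(300, 400), spacing_mm = 0.05,
                       mean_adu = 500, gain_coef = matrix(c(1, 0.05), 2, 1),
                       noise_sd_adu = 5, n_images = 10, seed = 1)
su <- snr_uniformity(flat$stack, block_px = 100)
su$nui
#> 0.0734
```

The NUI of 0.073 reflects the imposed gain gradient: SNR varies with the
gain because the noise level does not follow it. Batch runs over
directories of TIFF stacks or over the built-in presets are configured
with YAML via `run_report()`; `compare_reports()` tabulates DM-vs-SM
ratios and orderings. A thin command-line wrapper lives at
`inst/cli/mammoiq.R`.

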