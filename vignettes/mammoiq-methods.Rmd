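---
title: "Phantom image-quality metrics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom image-quality metrics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mammoiq evaluates the physical image quality of mammography systems from
repeated phantom acquisitions: uniformity of the signal-to-noise ratio,
the spectral structure and directionality of noise, low-contrast object
conspicuity, spatial resolution, and threshold contrast-detail
detectability. This vignette explains each model, the tunable parameters
and their defaults, what the synthetic generators do and do not emulate,
and the numerical choices made where the methodology is genuinely open.

## The data model

Every analysis consumes an `image_stack`: `n` co-registered 2-D images of
the same phantom plus the pixel pitch (Δx, Δy) in mm. Pixel values are
treated as given linear detector values ("ADU"); whether an acquisition
chain stores raw or display-processed values is outside the package's
knowledge, so no transfer-curve correction is applied. Noise analyses
need `n ≥ 2`; ten repeats is the conventional choice and the default in
the synthetic presets. Supported on-disk formats are grayscale TIFF and a
plain-text matrix format, each with a JSON sidecar carrying pitch and
label; the I/O layer deliberately stays thin and dependency-light.

Coordinates are 1-based `(row, col)` with rows along y and columns along
x; regions are `roi_spec(origin_row, origin_col, height, width)`. A
physical margin (`crop_margin`) is removed by rounding `margin_mm / Δ`
per axis to whole pixels — exact for the common 10 mm margin at both
0.05 mm and 0.10 mm pitch.

## SNR maps and the nonuniformity index

The per-pixel mean and standard deviation over repeats give
SNR(x, y) = μ/σ. The SD uses the sample (n − 1) convention — unbiased in
variance at n = 10 and consistent across all modules; with ten repeats
the per-pixel SNR estimate has a relative sampling error of roughly
1/√(2(n−1)) ≈ 24%, which is why the index below works on block means
rather than raw pixels. Pixels with σ = 0 carry no noise estimate; they
are flagged invalid and excluded from block means rather than zero-filled,
because zero-filling would drag the minimum block mean down artificially.

Blocks tile the map exactly (non-divisible dimensions are an error, not a
silent crop). The default block is 100 × 100 px at 0.05 mm pitch and
scales inversely with pitch (50 × 50 px at 0.10 mm), so the physical
block — 5 mm — is constant and indices from the two pitches are
comparable; a test asserts that the same continuous gain field sampled at
both pitches yields the same NUI within sampling error. The index,

NUI = (max PV̄ᵢ − min PV̄ᵢ) / ((max PV̄ᵢ + min PV̄ᵢ)/2),

is scale-invariant, so it does not matter whether it is computed on the
raw or max-normalized SNR map (asserted by a test); `normalize_map` exists
purely for display conventions. NUI is a global spread measure: it reacts
to the worst and best blocks only, and says nothing about the spatial
scale of the variation — a known limitation; local sliding-window
statistics are out of scope here.

## Noise power spectrum

Noise images are differences of same-condition acquisitions, which cancel
fixed-pattern structure and double the stochastic variance; the ½ factor
in

NPS(fx, fy) = ½ · (ΔxΔy)/(NxNy) · ⟨|DFT(ROIₙ − mean)|²⟩

undoes the doubling. Two pairing schemes are provided, because the
conventional "n noise images from n acquisitions" implies circular
consecutive differencing, whose overlapping pairs are correlated:
`"circular"` (default, n noise images) matches that convention, while
`"independent"` (⌊n/2⌋ disjoint pairs) is statistically clean and is what
the variance-sensitive tests and the acceptance script use. The per-ROI
mean is subtracted before the transform to suppress residual DC; no
apodization window is applied, since difference images have no gradients
by construction. The default ROI is a centered 128 × 128 region. For
white noise of per-acquisition SD σ the spectrum is flat at σ²ΔxΔy, and
integrating the spectrum over frequency (`nps_total_variance`) returns
σ² — the Parseval check used for validation.

The radial profile averages annuli of width one DFT bin (DC excluded) and
stops at the smaller axial Nyquist, beyond which annuli are incomplete.
Axial profiles follow detector-NPS practice: the lines adjacent to the
frequency axis (default half-width 3 per side) are averaged, the on-axis
line excluded by default, and ± frequencies folded. Anisotropy is
summarized as per-bin ratios of an axial profile to the radial profile
(radial values interpolated onto the axial bins) and tested with a
two-sided one-sample Wilcoxon signed-rank test of the log-ratios against
zero. The methodology behind published anisotropy p-values is typically
unnamed; the signed-rank choice makes no normality assumption, and a
simulation test confirms its rejection rate is ≈5% at α = 0.05 under
isotropic noise. Note that for noise low-passed along x the x-profile
falls *below* the radial average at every frequency (the radial average
mixes in high-power low-fx samples), while the y-profile sits above it —
both directions then reject, which is the physically correct reading of
a separable anisotropy.

## Mass CNR

CNR = (PV̄_signal − PV̄_background)/σ_background on a single local ROI
containing the mass, with the mass pixels masked out of the background.
Using the local surround rather than a distant background region keeps
edge-enhancement and halo artifacts of reconstructed images from biasing
σ_background. The default segmentation is geometric: smooth with a
Gaussian of a quarter of the mass radius, take the centroid of the
half-height core of the dominant extremum (bright or dark
auto-detected), and mask a disk of the nominal diameter inflated by 1.2 —
the inflation deliberately over-covers the halo. A blob is only accepted
when its smoothed amplitude exceeds 8 robust SDs of the smoothed
background; below that, the centroid is unstable and an error is raised.
An Otsu threshold alternative exists for irregular objects. The nominal
accreditation-phantom mass diameters {20, 10, 7.5, 5} mm are
configuration data (`acr_mass_diameters_mm`), not hard-coded; the
synthetic ordering presets scale them by 0.4 to {8, 4, 3, 2} mm so that
the largest mass fits a 300 px (15 mm at 0.05 mm pitch) local ROI with
background to spare — at full size, a 20 mm mass cannot leave background
pixels in a 15 mm ROI.

## Slanted-edge MTF

The edge angle is estimated per scan line as the centroid of the absolute
finite-difference profile within a window around its maximum, followed by
least-squares regression of position on line index. Lines whose step
estimate falls below five standard errors of the plateau difference are
rejected, which turns pure-noise inputs into errors instead of garbage
angles. The slanted geometry (recommended 0.5–5°; a warning outside)
de-phases the pixel sampling across lines, so pooling the signed
perpendicular distances of all pixels (all frames; the edge line is
re-regressed per frame) into bins of 0.1 pixel yields an oversampled
composite ESF. The bin width is a free parameter; refinement tests show
the downstream MTF is insensitive to it.

The composite ESF is fitted with ESF(x) = a + b·erf((x − x0)/(σ√2)) by
Levenberg–Marquardt with an analytic Jacobian and data-driven starting
values. The model regularizes low-contrast edges and makes the next step
exact: the LSF is the analytic derivative, a Gaussian of SD σ and area
2|b|, sampled at σ/20 over ±8σ, so no noise-amplifying numerical
differentiation is needed. The fit residual is reported because the erf
model cannot represent long-tailed scatter ESFs; a large residual is the
signal to distrust σ rather than a reason for the package to guess a
different model. The MTF is the zero-frequency-normalized modulus of the
LSF's DFT, zero-padded 8× for fine frequency sampling, reported to the
detector Nyquist 1/(2Δ); f50 and f10 are read off by linear interpolation
at the first downward crossing. For a Gaussian blur the whole chain has
the closed form MTF(f) = exp(−2π²σ²f²), hence f50 = √(ln 2/(2π²σ²)) —
the ground truth the generator emits and the recovery tests assert (2%
noise-free, 5% at 1% noise with 10 frames). Polarity, global gain, and
the exact angle within the recommended band do not move f50 by more than
1%.

Ten repeated edge frames are pooled at the ESF-binning stage rather than
averaged as per-frame MTFs: pooling uses all samples in one fit and is
the better-conditioned estimator at low contrast. A per-frame route can
be had by calling the chain on single-frame stacks.

## Contrast-detail scoring

The grid is 16 diameters × 16 gold thicknesses (defaults geometrically
spaced over 0.06–2.0 mm and 0.03–2.0 µm), each cell holding a center disk
plus one identical disk at a random corner. Published contrast-detail
analyses typically rely on a proprietary reader whose internals are not
specified; this package instead defines a transparent 4-alternative
forced-choice template observer: a zero-mean blurred-disk template
(blurred by the configured system PSF; rendered exactly via the
noncentral-χ² form of a Gaussian-blurred disk) is correlated at the four
corner positions and the argmax wins, ties resolving to the lowest index.
Zero-mean templates make the score invariant to local background. Because
the observer differs from any proprietary reader, absolute IQF⁻¹ values
are comparable only within this package; orderings and formula behavior
are the meaningful outputs. Grid jitter between acquisitions is handled
by registering cell centers to the generator-recorded offsets, not by
image registration — localization is not the quantity under test.

Detection fractions are thresholded at 62.5%, the midpoint between the
25% guess rate and 1. Two rules coexist deliberately: the CD curve uses a
psychometric fit p(t) = 0.25 + 0.75/(1 + exp(−k(ln t − μ))) solved at the
level (falling back to log-linear interpolation of the first crossing if
the fit fails), while D_{i,min} for IQF⁻¹ = 100/ΣCᵢ·D_{i,min} uses the
discrete smallest-detected-diameter rule, matching the quoted definition
of that index. Thresholds clamped at the sampled range are flagged rather
than extrapolated. Units in the sum are Cᵢ in µm times D_{i,min} in mm,
following the phantom's conventional ranges; the index is reported
unitless.

## The synthetic generators

The generators produce exactly the statistical structure the analyses
assume: flat fields as mean × polynomial gain field plus Gaussian noise
(optionally ∝ √gain, optionally colored by per-axis circular Gaussian
smoothing with the marginal SD rescaled back, so coloring changes only
spectral shape); edges as background + contrast·Φ(d/σ_psf) sampled at
pixel centers; masses as exactly-rendered Gaussian-blurred disks; and the
contrast-detail grid with per-image integer jitter (integer by default to
avoid interpolation confounds in observer tests). All are deterministic
under a seed. They do *not* emulate X-ray transport, scatter, detector
aperture integration, automatic exposure control, or any reconstruction
algorithm — so passing tests demonstrate correctness of the measurement
chain on its assumed signal model, not fidelity to any particular
clinical system.

The bundled study conditions (`mammo_preset`) contrast a DM-like mode
(0.05 mm pitch, σ_psf 0.08 mm, white noise SD 5 ADU, flat gain) with an
SM-like mode (0.10 mm pitch, σ_psf 0.17 mm, x-colored noise at 1.7× SD,
10% peak-to-valley gain gradient) — the qualitative signature of a
reconstructed synthetic 2-D image versus a native acquisition. Field
sizes (300 × 400 px flat fields, 256² edge ROIs, 300 px mass ROIs, the
full 16 × 16 grid at 4.8 mm cells, 10 repeats throughout) were chosen
once as the smallest sizes at which every estimator is comfortably inside
its asymptotic regime; `run_preset_analysis` runs the full suite per mode
in a few seconds. Under these conditions every expected ordering holds:
NUI_DM < NUI_SM, f50/f10 higher for DM, CNR_DM > CNR_SM at every
diameter, IQF⁻¹_DM > IQF⁻¹_SM, and the x-anisotropy test rejects for SM
only. The DM arm of that last check is a true null, so its p-value is
uniform by construction; ~5% of seeds will reject — the calibrated
behavior of an honest test, not a defect.

## Numerical notes and degenerate inputs

- Frequencies follow the DFT grid k/(NΔ), fftshifted to ±Nyquist; the
  unpaired −Nyquist line of even-length grids is dropped when folding.
- The erf and psychometric fits avoid the `nls` object machinery: its
  finite-difference derivative steps are relative to the parameter value
  and collapse when a parameter converges to ≈0 (as the edge location
  does on centered data), spuriously reporting a singular gradient.
  Direct Levenberg–Marquardt with explicit Jacobians has no such failure
  mode.
- Degenerate inputs fail loudly: zero-SD pixels invalidate SNR entries,
  all-invalid maps refuse to normalize, empty mask partitions and zero
  background SD are CNR errors, a featureless image is a segmentation
  error, all-equal anisotropy ratios are a degenerate test input, and a
  level never reached by the MTF returns the Nyquist flagged.

## Limitations

Absolute contrast-detail scores are observer-specific; DICOM input is not
supported (TIFF or text only); tomosynthesis projections, 3-D NPS/MTF,
NEQ/DQE, and human-observer threshold prediction are out of scope.
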