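---
title: "Simulating and quantifying narrow-band vessel-wall contrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying narrow-band vessel-wall contrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbicontrast)
```

## The problem

Narrow-band imaging (NBI) illuminates tissue with two narrow bands — blue
around 415 nm and green around 540 nm — chosen because haemoglobin absorbs
most strongly there. Haemoglobin-bearing structures (capillaries, and blood
accumulating at wall defects) therefore appear much darker under NBI than
under broadband white-light imaging (WLI), which spreads its energy across
wavelengths where haemoglobin is nearly transparent. In vascular endoscopy
this matters because an intact arterial intima is almost colourless: only
defects — dissection-type tears and thermal ablation burns — accumulate
blood, so NBI selectively boosts the contrast of exactly the structures an
interventionalist needs to see.

Quantifying that advantage requires co-registered WLI/NBI image pairs of the
same wall region, which ex vivo rigs produce but which are rarely archived.
`nbicontrast` therefore couples the analysis to a physics-based synthetic
generator: every claim the analysis makes can be exercised, end to end, on
scenes whose ground truth is known, and the same analysis functions accept
user-supplied co-registered image pairs.

## Image formation model

A scene is a frontal patch of vessel wall, rasterized as three fields: a
superficial haemoglobin concentration, a deep haemoglobin concentration
(both arbitrary units), and a base diffuse reflectance in [0, 1]. The
two-layer split encodes the wavelength dependence of penetration depth:
short (blue) wavelengths interact only with the superficial layer, longer
wavelengths also reach the deep layer. The fraction of the deep layer seen
at wavelength $\lambda$ is a piecewise-linear ramp

$$f(\lambda) = \mathrm{clip}\left(\frac{\lambda - 450}{150},\ 0,\ 1\right),$$

a deliberately minimal monotone encoding of "blue stays superficial, green
and red penetrate"; it is a package constant, overridable in
`band_transmission()`.

Each illumination band of centre $\lambda_0$ and full width at half maximum
$w$ is sampled at $K = 7$ wavelengths spaced across $\lambda_0 \pm w$ with
Gaussian weights $g_k$ (the band's line shape). Per pixel, the
band-integrated Beer–Lambert transmission is

$$T = \sum_{k=1}^{K} g_k \exp\!\big(-\mu(\lambda_k)\,
  [c_s d_s + f(\lambda_k)\, c_d d_d]\big),$$

with $\mu(\lambda)$ the absorption coefficient, $c_s, c_d$ the layer
concentrations and $d_s, d_d$ the layer path lengths. The rendered intensity
is

$$I = \mathrm{clip}\big(v \cdot R \cdot \textstyle\sum_b w_b T_b,\ 0,\ 1\big),$$

where $R$ is the base reflectance, $w_b$ the normalised band weights and $v$
a radial vignette. Scattering, specular highlights and colour reconstruction
are deliberately out of scope: the analysis operates on single-channel
intensity, and every qualitative property the package tests (NBI darkening
of haemoglobin, modality-equality at zero absorber, monotonicity in
concentration) already follows from this attenuation-only model.

Concentrations, depths and $\mu$ are all arbitrary units because only the
products $\mu c d$ enter the model; no physical calibration is attempted.

### The absorption table

The shipped table (`default_absorption()`,
`inst/extdata/hb_absorption_synthetic.csv`) is a synthetic curve: Gaussian
peaks centred exactly at 415 nm and 540 nm on a low flat baseline with a
trough near 650–700 nm. It is *not* literature haemoglobin data — it is
shaped only so that the narrow bands sit on absorption maxima, which is the
single property the method depends on. Users with calibrated spectra can
supply any two-column CSV (`wavelength_nm`, `mu`).

With the default table, the band-averaged absorption seen by the NBI
illumination (415/540 nm bands) is several times that seen by the 400–700 nm
broadband WLI — the physical origin of every contrast difference the package
measures.

## The synthetic scenes

`build_scene()` turns a `scene_spec` into rasters. Multiplicative texture is
seeded Gaussian noise smoothed to a stated correlation length and normalised
to unit standard deviation, so `texture_amplitude` is exactly the relative
standard deviation of the field. Three independent fields are drawn in a
fixed order (superficial hb, deep hb, reflectance); the reflectance field
uses 0.35 times the nominal amplitude, reflecting that wall tissue varies
less in intrinsic reflectance than in haemoglobin load. Identical specs
(including the seed) produce bit-identical maps, and scene construction
never perturbs the caller's RNG stream.

Lesions are soft-edged elliptical footprints applied in list order. Inside
the footprint, superficial haemoglobin is scaled towards `hb_multiplier`
times its value (blood accumulates at defects of either kind) and the
reflectance is shifted by `reflectance_delta` (negative for charred burns);
the edge blends out as a Gaussian over `edge_softness` pixels and is clipped
to exactly zero beyond four softness lengths, so lesions are strictly local.

The presets encode the four imaging scenarios the package targets:

| preset | phenotype | key parameters |
|---|---|---|
| `flushed_lumen` | saline-flushed wall, no defect | haemoglobin-free; texture + vignette only |
| `tear` | scalpel laceration | near-vertical ellipse 26 × 7 px, hb ×3, edge 2.5 px |
| `burn` | solder ablation burn | isotropic 16 px, hb ×4, reflectance −0.25, edge 4 px |
| `bifurcation_fiber` | branch viewed through a fibrescope | tear on the left + broad dark branch patch; fibre rendering on |

No published lesion dimensions exist for this preparation, so the sizes and
placements above are package choices. Two of them deserve justification. The
tear is oriented near-vertically (1.2 rad from the column axis) because the
ROI statistic differentiates along pixel rows: a longitudinal laceration
crosses almost every ROI row and contributes two sharp haemoglobin edges per
line profile, which is also how lacerations present in endoscopic views of a
vessel. And the default scales (scene 120 × 160 px, base superficial
haemoglobin 0.15 a.u. at unit path, texture amplitude 0.15 with 6 px
correlation, sensor noise 0.01) were chosen once so that the absorption
signal — not sensor noise — dominates the gradient statistic, emulating the
good-quality rigid-scope images such comparisons are computed on.

What the generator does *not* emulate: tubular geometry and perspective,
specular reflections from wet tissue, colour appearance (brown surface
capillaries vs cyan deep vessels), flushing dynamics, motion or shot noise.
Passing tests therefore demonstrate correctness of the statistic and the
qualitative physics of band-selective absorption contrast; they do not
certify performance on clinical images.

## The ROI gradient statistic

Given a co-registered pair and one rectangle (0-based, half-open) applied
identically to both modalities:

1. `extract_roi()` crops the ROI verbatim; each pixel row is one *line
   profile* (intensity vs column).
2. `profile_gradients()` takes signed first differences along each row:
   `g[r, c] = p[r, c+1] - p[r, c]`.
3. `mean_intensity_change()` averages `|g|` over the ROI — the per-modality
   average intensity change.
4. `percent_increase()` reports `100 * (NBI - WLI) / WLI`.

Two interpretation choices are built in. First, the per-row "line profile"
is the spatial intensity trace itself, not a binned histogram — gradients
are only meaningful for spatial profiles. Second, the *absolute* gradient is
averaged: signed first differences of near-periodic texture cancel towards
zero, which would make any cross-modality comparison meaningless, whereas
the mean absolute gradient is a total-variation-type quantity that grows
with edge content and is orientation-independent in sign.

The statistic obeys exact algebra that the test suite asserts: invariance
under additive offsets, homogeneity of degree one under gain (hence the
percent increase is invariant to a common gain on both modalities), zero
exactly on row-wise constant ROIs, and `|s|` exactly on a column ramp of
step `s`. No normalisation is applied between modalities by default — the
raw statistic compares raw images, and NBI is physically dimmer. An optional
`normalize = TRUE` divides each ROI by its own mean for a gain-free
comparison; it is off by default because the default comparison should show
the method as a camera sees it.

The percent increase depends on the ROI: it should cover the lesion *and*
surrounding tissue. A lesion-only ROI measures internal lesion texture; a
background-only ROI measures nothing relevant. `preset_roi()` records the
choice used for each preset.

## Sensor noise and the fibre bundle

Sensor noise is additive Gaussian (standard deviation as a fraction of full
scale, default 0.01) drawn independently per modality and clipped — simpler
than shot noise and sufficient for a contrast statistic that averages
thousands of gradients. Noise enters both modalities' denominators of the
percent increase, so it systematically dilutes the measured uplift; the
uplift figures reported by this package are therefore tied to the stated
noise level.

`apply_fibre_bundle()` emulates a low-fibre-count flexible endoscope:
intensities are averaged over ~`n_fibres` hexagonally packed cores (each
pixel contributes to its nearest core), the core mosaic is re-smoothed with
a Gaussian of half the core pitch (inter-core interpolation), scaled by
`brightness_factor` and clipped. The default 5000 cores matches the
fibre count of small vascular fibrescopes; `brightness_factor = 0.7`
encodes that fibre images are dimmer, but no photometric measurement backs
the exact value — it is an uncalibrated package choice. The operation is a
spatial low-pass: it can only reduce the ROI mean absolute gradient of a
noiseless render, a property the acceptance tests verify per seed.

## Numerical and reproducibility choices

* **Smoothing** is an FFT-domain periodic Gaussian filter (multiplying the
  2-D spectrum by $\exp(-2\pi^2\sigma^2|f|^2)$): exact for any sigma and
  image size, with no kernel truncation. The periodic boundary makes texture
  wrap, which is immaterial for statistics computed on interior ROIs.
* **Seeding**: every stochastic step runs under `with_seed()`, which
  restores the caller's RNG state. Replicate seeds derive from a base seed
  by a counter-based two-step MINSTD recurrence (`child_seed()`), exact in
  doubles and always below $2^{31}$, so any single replicate can be re-run
  in isolation.
* **Determinism**: identical `scene_spec`s give bit-identical maps;
  identical `run_config`s give byte-identical CSV outputs.
* **Quantization**: images are written at 8-bit (PNG) or 8/16-bit (TIFF)
  grayscale with linear full-range mapping; `quantize_intensity()` exposes
  the exact grid so on-disk analysis can be compared bit-for-bit with
  in-memory analysis of quantized values.
* **Degenerate inputs** fail fast with named bounds: ROIs need at least two
  columns, the percent increase refuses a non-positive WLI baseline, lesions
  wholly outside the frame are rejected, and bands outside the absorption
  table's span are errors rather than silent clamps.

## The uplift-recovery calibration

`recover_uplift(target)` asks: what lesion haemoglobin multiplier makes the
tear scenario's mean percent increase equal a target? It evaluates the mean
over a fixed set of replicate seeds (so the objective is a deterministic,
smooth function of the multiplier), verifies on a coarse grid that the
objective is non-decreasing and brackets the target — failing with the
bracketing values if not — and then bisects. The calibrated scene is
returned as an ordinary `scene_spec` usable as an inline scenario.

A target of 20% is used as the package's worked example, a mid-range
effect size for this kind of modality comparison. With the default study
conditions the tuned multiplier lands near 3.4 — comfortably inside the
physiologically plausible range for blood accumulation at a fresh defect —
on the steep part of the uplift curve, far from its saturation plateau.
Problem sizes used throughout the examples and tests: 120 × 160 px scenes,
a 50 × 70 px ROI, 100 calibration replicates with a 0.15-point bisection
tolerance, and 50 fresh seeds for out-of-sample evaluation of the
calibrated scenario — enough replicates that the standard error of a
reported mean uplift is a few tenths of a point.

## Known limitations

* Attenuation-only optics: no scattering, so deep-layer contrast is purely
  a transmission effect and the cyan/brown colour phenomenology of real NBI
  is not reproduced (nor needed for the intensity statistic).
* The absorption table is synthetic; absolute uplift magnitudes are
  meaningful only relative to the package's own study conditions.
* The percent-increase statistic is ROI-dependent by construction; external
  users must choose and report their ROI.
* Co-registration of external pairs is assumed, not verified; misregistered
  pairs inflate both modalities' gradients unpredictably.
* Noise is Gaussian-additive; at very low light (fibre imaging) real sensors
  are shot-noise limited, which this model understates.
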