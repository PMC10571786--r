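---
title: "Simulating narrow band imaging by statistics transfer in lαβ space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating narrow band imaging by statistics transfer in lαβ space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbisim)
```

## The model

Narrow band imaging (NBI) renders mucosa with darker, higher-contrast
vessels than white-light imaging (WLI) because the illumination bands sit
on hemoglobin absorption peaks. Capsule endoscopes have no NBI hardware,
so `nbisim` approximates the NBI *appearance* in post-processing by global
color-statistics transfer: the WLI frame is moved into a color space whose
axes are (nearly) statistically independent, and on each axis its mean and
standard deviation are replaced by those of an NBI reference.

The space is Ruderman's lαβ: RGB is mapped to LMS cone responses by a
fixed 3×3 matrix, the cone responses are log10-transformed to remove their
characteristic skew, and the logged channels are decorrelated by the
orthogonal-scaled map

$$ l = \tfrac{L+M+S}{\sqrt3},\quad
   \alpha = \tfrac{L+M-2S}{\sqrt6},\quad
   \beta  = \tfrac{L-M}{\sqrt2}. $$

On each axis independently, with source statistics $(\mu_s, \sigma_s)$ and
target statistics $(\mu_t, \sigma_t)$:

$$ x' = (x - \mu_s)\,\frac{\sigma_t}{\sigma_s} + \mu_t . $$

The printed form of the transfer in the literature shows only the scaling
of the mean-subtracted values; the target mean must be added back for the
output statistics to equal the target's, which is the stated goal of the
method, so the package implements the full affine map. The inverse chain
(decorrelation inverse, `10^x`, inverse cone matrix, gamut clip) returns a
displayable frame.

**Assumptions.** The transfer is purely global: it assumes the source and
reference have broadly comparable composition (mucosa filling most of the
frame). Frames dominated by flare, bubbles, or black borders violate this,
which is exactly what the degradation metrics below quantify. The method
does not model the NBI illumination spectrum; it reproduces a *look*, not
radiometry.

## Parameters that matter

* **`floor`** (default `1/255`, unit-range LMS): clamp applied before the
  logarithm. Endoscopy frames contain true black (borders, vignetting), at
  which `log` is undefined; one 8-bit quantization step is the smallest
  value distinguishable in the input. Larger floors compress shadow detail.
* **Population vs sample SD**: statistics use the population (1/N) form so
  that imposing statistics is exact and idempotent to machine precision;
  at 640×480 the two differ by a factor of ~1.000002.
* **`mask_mode`** (`"none"` default, `"auto_border"`): optionally exclude
  pixels with luminance < 10/255 from the *statistics* (the transfer is
  still applied everywhere). The default is off because the plain
  equations make no masking assumption; turn it on for circular
  field-of-view capsule frames.
* **Reference**: one frame, several frames (their *pixels* are pooled
  before computing statistics — pooling is the well-defined generalization,
  unlike averaging per-frame statistics), or a precomputed JSON statistics
  file for users who have published statistics but no reference frame.
* **Gamma**: inputs are treated as linear RGB after division by 255. No
  sRGB linearization is applied; the conversion is a display-space
  recoloring, and this is a documented limitation.

## Degenerate and numerical cases

* A source axis with zero standard deviation (constant-color frame) makes
  the scale ratio undefined; that axis is mapped uniformly to the target
  mean rather than failing.
* Out-of-gamut results (common when saturated highlights are pushed toward
  a darker palette) are clipped to [0, 1]; the clipped fraction is
  reported on every simulation and logged as a warning in batch runs.
* A lab value large enough to overflow `10^x` is capped at `10^300` and
  ends up clipped; no non-finite value can propagate.
* Quantization to 8 bits happens exactly once, on write, rounding half-up.
* The forward/inverse chain is exact to ~1e−15 away from the clamp and the
  gamut clip; the package commits to 1e−6.

## SSIM, PSNR, entropy

SSIM uses the standard configuration — BT.601 grayscale, 11×11 Gaussian
window with σ = 1.5, K1 = 0.01, K2 = 0.03, dynamic range 255 — with local
windows fully inside the image, matching the original formulation and the
naive double-loop oracle the tests compare against. SSIM is stored in
[−1, 1] and reported to users as a percentage. PSNR is
`10·log10(255²/MSE)` over all three channels, with identical frames
reported as `inf` rather than capped. Entropy is the Shannon entropy of
the 256-bin gray-level histogram in bits; the batch report carries both
the absolute difference in bits and the difference relative to the WLI
entropy as a percentage, since both conventions appear in practice.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` describes a 640×480 frame (the typical capsule frame
size): a smooth mucosa-colored background (coarse Gaussian grid,
bilinearly upsampled), slow independent per-channel chromaticity drift so
the α and β axes carry genuine variance (without it the fixture would be a
single chromaticity modulated by shading, and the chromatic σ_t/σ_s would
be a quotient of rounding noise), random-walk vessel strokes with Gaussian
cross-section, elliptical saturated highlights accumulated until the
requested coverage is reached, an optional circular field-of-view border,
and optional Gaussian blur. Under white light, vessels attenuate green and
blue more than red (hemoglobin); under the NBI palette they attenuate all
channels, at 1.6× the contrast, on a darker green-shifted base — palette
centers (0.80, 0.55, 0.52) and (0.35, 0.50, 0.42) are fixture constants,
chosen once for qualitative resemblance.

Randomness is pinned to Mersenne-Twister with inversion sampling, seeded
per frame, so fixtures are bit-reproducible and the caller's RNG stream is
left untouched.

What the generator does **not** emulate: real mucosal texture spectra,
lesions, specular geometry of wet tissue, sensor noise, compression
artifacts, or the actual spectral relationship between WLI and NBI
illumination. Green tests on fixtures therefore demonstrate the
*correctness of the algorithm and its metrics*, not clinical fidelity of
the converted frames. In particular, the fixture NBI palette differs from
the WLI palette far more than a real WLI/NBI pair of the same scene
differs photometrically, so PSNR on fixtures (≈11 dB) is much lower than
values reported for clinical conversions; SSIM, which is built from local
structure rather than absolute levels, lands near 93% on fixtures.

## Evaluation protocol and problem sizes

The batch protocol mirrors the common evaluation design: 50 frames are
converted against one reference and the CSV report carries one row per
frame plus a trailing `MEAN` row. The test suite exercises the property
set at small sizes (16–64 px frames for oracles, 100-repetition property
loops) and the full 640×480, 50-pair protocol once; `scripts/acceptance.R`
re-runs the 50-pair protocol from scratch at 640×480 and writes the
per-metric means as JSON. Degradation behavior — the observation that
blurred or flare-laden sources convert worse — is tested as a trend: over
5-level blur and highlight series, SSIM between the degraded source and
its simulated NBI must be non-increasing with at most one inversion.
Mechanistically, blur shrinks the source's per-axis standard deviations so
the transfer over-amplifies residual contrast, and saturated highlights
both bias the source statistics and land far from the imposed palette.

## Design choices that were genuinely open

* **Decorrelation matrix**: not printed in the endoscopy literature that
  motivated this package; the Reinhard/Ruderman factorization
  `diag(1/√3, 1/√6, 1/√2) · [[1,1,1],[1,1,−2],[1,−1,0]]` is used, as that
  is the matrix of the cited color-transfer method.
* **Log base**: base 10, matching the same method. The transfer is
  invariant to the base (it rescales all statistics on an axis equally),
  so this affects only intermediate values.
* **RGB→LMS route**: the single combined matrix is applied directly rather
  than a two-step RGB→XYZ→LMS product, and its inverse is obtained by
  numerically inverting that matrix once at load time.
* **Entropy on grayscale**: the texture-entropy convention; color-channel
  entropy would triple-count correlated structure.
* **Config files**: the CLI accepts YAML for batch configuration, chosen
  over TOML for availability of a mature parser in the R ecosystem.

## Known limitations

Global statistics transfer cannot adapt to composition mismatch between
source and reference (the classic grass-vs-sky failure); region-wise or
swatch-based transfer is out of scope. No ICC color management or camera
calibration is performed. The NBI illumination spectrum is not modeled, so
converted frames are an appearance simulation only.
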