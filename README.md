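# nbisim

Simulated narrow band imaging (NBI) for white-light endoscopy frames.

## The problem

Narrow band imaging illuminates the mucosa at ~415 nm and ~540 nm, the
absorption peaks of hemoglobin. Vessels absorb strongly at those bands and
appear dark against the mucosa, which makes early neoplastic lesions far
easier to see than under broadband white-light imaging (WLI). Video capsule
endoscopes cannot carry NBI hardware, so an NBI-like rendering must be
produced in post-processing from the WLI frames. `nbisim` is for engineers
and researchers who need that conversion as a reproducible, tested building
block — plus the standard metrics to judge how faithful the conversion is.

## The algorithm

The conversion is per-axis statistics transfer in Ruderman's decorrelated
lαβ color space:

1. **RGB → LMS.** Each pixel is mapped to cone responses with the standard
   3×3 conversion matrix

   ```
   L   0.3811 0.5783 0.0402   R
   M = 0.1967 0.7244 0.0782 · G
   S   0.0241 0.1288 0.8444   B
   ```

2. **Log transform.** `L ← log10 L`, etc., after clamping at a small floor
   (default 1/255) so black pixels stay finite. The log removes most of the
   skew of cone responses.

3. **Decorrelation.** `l = (L+M+S)/√3`, `α = (L+M−2S)/√6`, `β = (L−M)/√2`.
   The axes separate luminance from the yellow–blue and red–green opponent
   channels and are nearly uncorrelated in natural scenes.

4. **Statistics transfer.** With per-axis means `μ` and population standard
   deviations `σ` of the source (WLI) and target (NBI reference):

   `x′ = (x − μ_s) · (σ_t / σ_s) + μ_t`   for each axis independently.

5. **Inverse chain** back to display RGB, clipping to gamut.

Because the axes are decorrelated, matching first and second moments
axis-by-axis recolors the frame toward the NBI look without channel
cross-talk. The quality of a converted frame is assessed with SSIM
(11×11 Gaussian window, the standard Wang et al. configuration), PSNR
(dB, 8-bit scale), and the absolute difference of 256-bin gray-level
Shannon entropies.

Since clinical WLI/NBI data cannot ship with a package, `nbisim` includes a
deterministic synthetic frame generator (smooth mucosa background, dark
curvilinear vessels, specular highlights, optional blur and circular
field-of-view border) that renders the same seeded anatomy under a
white-light and an NBI-like palette.

## Worked example

```r
library(nbisim)

spec <- synthetic_spec(seed = 7)          # 640x480 synthetic WLI/NBI pair
pair <- generate_pair(spec)
sim  <- simulate_nbi(pair$wli, pair$nbi_ref)
print(sim$tgt_stats)
#> l-alpha-beta channel statistics (307200 pixels)
#>               l       alpha          beta
#> mean -0.6422306 0.019461299 -0.0168090018
#> sd    0.1186623 0.004310861  0.0007530021

evaluate_pair(pair$wli, quantize_unit(sim$image), image_id = "frame_007")
#>   image_id   ssim ssim_pct psnr_db entropy_wli_bits entropy_nbi_bits
#>  frame_007 0.9367    93.67   11.28            4.679            4.978
#>  entropy_diff_bits entropy_diff_pct
#>             0.2989            6.387
```

The target statistics are the six numbers (per-axis mean and standard
deviation) that define the NBI look being imposed. The report says the
simulated frame keeps 93.67% of the source's local structure (SSIM), sits
11.3 dB from it in raw pixel terms (PSNR is low because the NBI palette is
deliberately much darker and greener than the source), and changes the
gray-level information content by 0.30 bits (6.4% of the source entropy).

A command-line interface wrapping the same functions is installed at
`inst/exec/nbisim`:

```sh
Rscript inst/exec/nbisim fixtures --out-dir fx --pairs 10 --seed 1
Rscript inst/exec/nbisim stats --reference fx/nbi_ref_001.png --out ref.json
Rscript inst/exec/nbisim batch --sources 'fx/wli_*.png' --stats ref.json --out-dir out
```

`batch` writes each simulated frame and a CSV report with one row per frame
and a trailing `MEAN` row.

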