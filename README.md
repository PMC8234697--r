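# ccfd — choriocapillaris flow-deficit quantification from en face OCTA

`ccfd` quantifies flow deficits (FDs) of the choriocapillaris — the
capillary layer under the retinal pigment epithelium — on 3 × 3 mm en face
swept-source OCT-angiography slabs, for researchers studying
age-related macular degeneration (AMD) and aging of the choroidal
microvasculature. It implements the standard Fiji-style analysis chain as
tested, scriptable R code, together with the cohort statistics used to
relate FD metrics to clinical covariates, and a synthetic-scene generator
with known ground truth so that every stage is testable without patient
data.

## The method

For each eye, a co-registered *flow* slab and *structure* slab are
processed as follows:

1. **Drusen-shadow compensation.** Drusen attenuate the OCT beam and darken
   both slabs beneath them; uncorrected, these shadows are miscalled as
   flow deficits. The flow slab is multiplied pixelwise by the
   Gaussian-smoothed inverse of the structure slab (bright exactly where
   shadows fall), then min–max rescaled to [0, 1]:
   `C = rescale( F · G_σ(1 − S) )`, with σ = 2 px by default.
2. **Phansalkar local thresholding** over a circular window of radius *r*
   (default 15 px; 4, 8 and 10 px in the sensitivity analysis):

   `T = m · (1 + p·e^(−q·m) + k·(s/R − 1))`,

   where *m*, *s* are the local window mean and population SD and
   `k = 0.25, R = 0.5, p = 2, q = 10`. A pixel is flow iff its intensity
   exceeds *T*; otherwise it is a flow deficit.
3. **Particle metrics.** Deficits are the 8-connected components of the
   binary mask (no size/circularity filtering): FD% (deficit area over
   image area), FD count, mean FD size (µm²), total FD area (mm²), with
   areas converted through the pixel pitch (3000/512 ≈ 5.859 µm/px by
   default; physical window radius = `(r + 0.5) × pitch`, so r = 15 px ↦
   90.82 µm).
4. **Cohort statistics.** Group summaries (mean ± SD), two-sided Fisher
   exact tests for binary flags, Mann–Whitney tests for quantitative
   variables, an OLS fit of log₁₀(FD count) on log₁₀(FD size), and a
   univariate screen (p < 0.20) feeding a multivariate linear regression of
   log₁₀ FD metrics on age, BCVA, CMT, CT (log₁₀) and drusen/atrophy flags.

## A worked example

Six synthetic eyes, quantified at all four analysis radii:

```r
library(ccfd)

dir <- tempfile(); out <- tempfile()
manifest <- writeSyntheticScenes(6, dir, seed = 1)      # flow/structure TIFF pairs
cohort <- generateCohort(nEyes = 6, seed = 1, neovascularPrevalence = 0)
cohort$eye_id <- manifest$eye_id
res <- runPipeline(manifest, cohort = cohort, radii = c(4, 8, 10, 15),
                   outDir = out)
res$perRadius[, c("radius_px", "radius_um", "fd_percent_mean",
                  "n_fd_mean", "mean_fd_size_um2_mean")]
#>   radius_px radius_um fd_percent_mean n_fd_mean mean_fd_size_um2_mean
#> 1         4     26.37           37.72      4928                 688.9
#> 2         8     49.80           41.01      3295                1120.2
#> 3        10     61.52           42.06      2618                1446.1
#> 4        15     90.82           43.35      1647                2369.3
```

Reading the table: each row is one window radius with its micron
equivalent; across the cohort, FD% grows slightly with the radius while the
deficit count falls and the mean deficit size rises — smaller windows
fragment the deficit map into more, smaller particles. Per-eye metrics for
a single scan:

```r
fl <- readEnface(manifest$flow_path[1], modality = "flow", eyeId = "scene001")
st <- readEnface(manifest$structure_path[1], modality = "structure",
                 eyeId = "scene001")
computeMetrics(binarize(compensate(fl, st)))
#> FDMetrics (eye scene001)
#>   FD%:            43.29
#>   FD count:       1651
#>   mean FD size:   2359.76 um^2
#>   total FD area:  3.8960 mm^2
#>   (radius 15 px, pitch 5.859 um/px)
```

So 43.29% of this 3 × 3 mm scan is flow deficit, split over 1651 connected
deficits averaging ~2360 µm², totalling 3.90 mm². `runPipeline()` also
writes the per-eye metrics CSV, the per-radius summary, group-comparison
and regression reports, and a run manifest with the configuration hash so
reruns are byte-identical.

See `vignettes/choriocapillaris-flow-deficits.Rmd` for the model, the
parameter choices and what the synthetic generator does and does not
emulate.

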