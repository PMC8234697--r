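---
title: "Quantifying choriocapillaris flow deficits on en face OCTA"
author: "ccfd package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choriocapillaris flow deficits on en face OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfd)
```

## The measurement problem

The choriocapillaris (CC) is the capillary bed that feeds the retinal
pigment epithelium. On swept-source OCT angiography, a thin en face slab
taken a few tens of microns below the RPE shows the CC flow signal; regions
with no detectable flow — *flow deficits* (FDs) — appear as dark patches.
Their prevalence grows with age and with age-related macular degeneration,
so per-eye FD statistics (FD%, FD count, mean FD size, total FD area) are a
useful quantitative phenotype in fellow eyes of exudative AMD.

Two properties of these slabs drive the design of the pipeline:

* **They are dim, low-contrast images.** The decorrelation signal does not
  span the detector's dynamic range, and deficits sit close to the noise
  floor. A single global threshold fails; the field uses the Phansalkar
  local threshold, which was designed for exactly this regime.
* **Drusen cast shadows.** Sub-RPE deposits attenuate the OCT beam, darkening
  both the structure and the flow slab beneath them. Unless corrected, these
  shadows are miscalled as flow deficits.

## The pipeline

For each eye, co-registered flow and structure slabs on the same pixel grid
are processed as:

1. **Shadow compensation** — invert the structure slab (`1 - v`), smooth it
   with a Gaussian (`blurSigmaPx`, default 2 px), multiply pixelwise into
   the flow slab, and min–max rescale the product to [0, 1]. Because drusen
   darken the structure slab, its smoothed inverse is bright exactly under
   drusen and boosts the attenuated flow signal there. For a multiplicative
   shadow `a` on both channels and a structure level `b`, the residual
   brightness ratio after compensation is `a (1 - ab) / (1 - b)`, which is
   within a few percent of 1 for mid-gray slabs (`b` near 0.6) at moderate
   attenuation — the regime of real data.
2. **Binarization** — the Phansalkar threshold over a circular window of
   radius `radiusPx` (default 15 px):
   `T = m (1 + p e^{-q m} + k (s / r - 1))`, with `m`, `s` the local window
   mean and population SD and constants `k = 0.25`, `r = 0.5`, `p = 2`,
   `q = 10` from the original publication. A pixel is *flow* iff its
   intensity strictly exceeds `T`; ties go to deficit. Window boundaries are
   handled by reflection.
3. **Particle metrics** — 8-connected components of deficit pixels, with no
   size or circularity filtering. FD% is deficit pixels over all pixels;
   component areas convert to µm² via the squared pixel pitch, so
   `nFD × meanFDSizeUm2` equals the total deficit area exactly.
4. **Radius sensitivity** — the same slabs re-binarized at radii 4, 8, 10
   and 15 px. Smaller windows fragment the deficit map into more, smaller
   components; the per-radius table makes the dependence explicit.

### Geometry and units

The scan covers 3 × 3 mm. The raster size is configurable; the default is
512 × 512 px, hence a pitch of 3000/512 ≈ 5.859 µm/px. This is the unique
pitch under which the centre-pixel-inclusive radius conversion
`(radiusPx + 0.5) × pitch` reproduces the four conventional micron
equivalents of the analysis radii to two decimals:

```{r}
data.frame(radius_px = c(4, 8, 10, 15),
           radius_um = round(radiusPxToUm(c(4, 8, 10, 15)), 2))
```

The plain `radius × pitch` convention does not reproduce them, which is why
the half-pixel convention is fixed in `radiusPxToUm()`.

### Numerical choices

* Intensities are normalized to [0, 1] at load (`raw / (2^bitdepth - 1)`):
  the exponential term of the Phansalkar formula assumes a bounded scale.
* Thresholding runs at full float precision; an 8-bit pipeline could shift
  a small number of borderline pixels.
* Gaussian kernels are sampled, truncated at 4σ and renormalized; blur and
  window statistics both use symmetric (edge-repeating) reflection at the
  frame, avoiding edge darkening that would inflate FD% at the border.
* `σ` in the threshold is the population SD of the window, matching
  reference implementations of the method.
* The blur σ of the compensation is not standardized in the literature; 2 px
  is a common smoothing choice and is exposed as a parameter, so its effect
  can be studied directly.
* Min–max rescaling after multiplication emulates the 32-bit product plus
  autoscaled 8-bit conversion of the usual Fiji workflow and makes the
  absolute intensity scale reproducible, which matters because the
  exponential term is not scale-invariant.
* A constant product (degenerate input) rescales to all zeros, and an
  intensity exactly equal to its threshold is classified deficit; both
  choices are documented and tested.

## The synthetic-data generator

No patient scans ship with the package; `generateScene()` builds slab pairs
with known ground truth instead.

* **Deficit geometry**: a Gaussian white-noise field smoothed at
  `fdTextureScalePx` (default 4 px) and thresholded at the quantile that
  yields `targetFdFraction` (default 0.45). Quantile thresholding gives
  exact area-fraction control, and smoothed-noise level sets give the
  irregular morphology of real deficit maps (unlike placed ellipses).
* **Intensities**: flow pixels at 0.30, deficit pixels at 0.10, structure
  at 0.65, additive Gaussian noise of SD 0.04. These emulate the dim,
  low-contrast character of real CC flow slabs — deficits near the noise
  floor — which is precisely the regime in which drusen shadowing corrupts
  an uncompensated analysis and in which the compensation earns its keep.
  With high-margin synthetic scenes (bright flow, dark deficits, wide gap)
  the local threshold alone absorbs shadows and the compensation would look
  superfluous; such scenes do not represent real slabs.
* **Shadows**: 16 discs with radii 20–60 px (≈120–350 µm: large drusen to
  drusenoid PEDs) at attenuation 0.6, jointly covering about a fifth of the
  field, multiplied into *both* channels — the same field, as for a real
  absorber above the slab.
* **Cohorts**: `generateCohort()` samples age, BCVA, CMT, CT and the five
  flags from distributions matching a fellow-eye AMD cohort (mean age 80,
  drusenoid PED prevalence ≈0.45, …) and generates metrics from planted
  linear models on the log10 design used by `regressionScreen()` (effects
  of realistic magnitude: age 0.62 and small drusen −0.13 on log10 FD%;
  age 2.69 and CT −0.68 on log10 size), with size and count coupled through
  a planted log–log law (slope −0.0604, log10 intercept 3.52, chosen so a
  mean size near 5000 µm² implies a count near 2000).

What the generator does *not* emulate: OCTA speckle statistics, projection
artifacts, segmentation errors of the slab, vessel texture of the flow
signal, or spatially varying signal strength. Passing the recovery and
shadow-robustness tests therefore shows that the algorithmic chain is
correct and self-consistent under its stated model, not that any particular
clinical FD% value is accurate on device data.

## What the tests establish

* **Oracle equivalence**: the fast windowed statistics and the separable
  blur match brute-force per-pixel loops (≤1e−9 and 1e−6 respectively), and
  component labelling matches a flood fill.
* **Ground-truth recovery**: on noise-free, high-contrast scenes the
  end-to-end pipeline recovers planted deficit fractions of 0.2/0.4/0.6
  within 5 points of FD%.
* **Shadow robustness**: at attenuation 0.6, compensated FD% stays within
  2 points of the unattenuated run, while binarizing the raw flow slab
  (skipping compensation, hence also its rescale — what a user binarizing
  the raw export would do) differs by more than 5 points. This is the
  package's demonstration of the compensation's purpose.
* **Statistics layer**: the two-sided Fisher test (minimum-likelihood rule,
  computed from the hypergeometric distribution, zero-margin convention
  p = 1) matches exhaustive enumeration for all margins ≤ 12 and the
  independent `stats::fisher.test`; the Mann–Whitney wrapper uses the exact
  distribution for combined n ≤ 20 without ties and the tie/continuity
  corrected normal approximation otherwise; planted regression effects are
  recovered within their 95% CIs in ≥90% of simulated cohorts.

Problem sizes in the default test run are the package's own choices: scenes
at 512 px where a property concerns the default geometry (recovery, shadow
robustness, the radius sweep over a 20-scene cohort), 64–128 px where it
does not (oracle equivalence, pipeline smoke tests), and 100 simulated
cohorts of 89 eyes for regression coverage.

## Design decisions that were genuinely open

* **Window shape**: circular (centre distance ≤ radius), matching the
  reference Auto Local Threshold behaviour that the micron conversions
  assume; a square window would change the radius semantics.
* **Connectivity**: 8-connected components, the particle-tracer default;
  4-connectivity would materially raise the count. (The installed image
  library's labeller is 4-connected, so labelling is implemented in the
  package's compiled code.)
* **Component filtering**: none — the size 0–∞, circularity 0–1 bounds pass
  everything, and no frame-touching exclusion is applied.
* **Cohort "size" summary**: the per-radius table reports the mean across
  eyes of each eye's mean component area (not the pooled component mean);
  pooled statistics can be derived from `componentSizesPx()`.
* **Univariate screen**: covariates enter the multivariate stage at
  univariate p < 0.20. The conventional "and/or clinical significance"
  escape clause is replaced by an explicit `forceIn` list (default empty)
  for reproducibility. No multiple-testing correction is applied, matching
  standard practice for this screen.
* **Log–log intercept**: reported on the log10 scale. (Published values of
  this intercept are sometimes printed on an ambiguous scale, e.g. in the
  thousands on a log10–log10 plot; the package does not attempt to guess a
  different axis convention.)

## Known limitations

* The compensation is the field's invert–blur–multiply scheme, not a
  physical attenuation model; it under- or over-corrects when the structure
  slab level is far from mid-gray.
* Metrics are whole-image only; no ETDRS-subfield or topographic analysis.
* The Mann–Whitney exact path is limited to small tie-free samples, as in
  standard implementations.
* Synthetic scenes are stationary; real slabs have spatially varying signal
  quality that the generator does not model.

## A worked run

```{r, eval = FALSE}
dir <- tempfile(); out <- tempfile()
manifest <- writeSyntheticScenes(6, dir, seed = 1)
cohort <- generateCohort(nEyes = 6, seed = 1, neovascularPrevalence = 0)
cohort$eye_id <- manifest$eye_id
res <- runPipeline(manifest, cohort = cohort, radii = c(4, 8, 10, 15),
                   outDir = out)
res$perRadius[, c("radius_px", "fd_percent_mean", "n_fd_mean")]
```
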