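---
title: "Removing vertical band defects from mammograms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing vertical band defects from mammograms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deband)
```

## The problem

A failing column of a digital mammography detector leaves a vertical band
artifact: a sharp intensity rise inside the band (in the worst case full
saturation at 255, i.e. complete loss of information), an intensity ramp
that decays into the flanking tissue — brighter on one side, darker on the
other — and a visible loss of contrast on one side of the band. Such
images are normally discarded; the goal of this package is to restore them
well enough that both radiological reading and quantitative (radiomics)
analysis remain trustworthy.

Everything operates on 8-bit grayscale rasters (`gray_image`): plain
integer matrices in `[0, 255]`, row 1 at the top, 1-based column indices,
and half-open `[left, right)` column intervals throughout.

## Pipeline

`restore_pipeline()` chains the stages; each is exported on its own.

1. **Breast contour** (`find_breast_contour`). Per image row, scan inward
   from both vertical borders until a pixel exceeds a low threshold
   (default 5); the row's breast run is the interval between the two first
   hits. This is deliberately simple — the background of a mammogram is
   true black — and rows with no hit stay empty.
2. **Defect core** (`detect_defect_core`). Core pixels are in-mask pixels
   with intensity strictly above 220 or exactly 0: the part of the band
   where the detector destroyed information outright. Per row the tightest
   interval around the qualifying run is kept; when several disjoint runs
   occur, the one nearest the median core column wins, because the defect
   is a single vertical structure and isolated bright specks are noise.
   The 220/0 test is applied to the raw 8-bit input; whether any
   normalization should precede it is not standardized, so none is
   applied.
3. **Core connection** (`connect_core_segments`). The band's brightness
   can dip below the core threshold mid-band, leaving core segments only
   near the ends. Missing rows between the topmost and bottommost
   intervals get bounds linearly interpolated in the row index (rounded
   half-up). The operation is idempotent and never shrinks an interval.
4. **Ramp flattening** (`tile_flanks`, `column_baseline`, `flatten_ramp`,
   driver `correct_ramp`). Both flanks are tiled with curvilinear
   quadrilaterals of nominal size 100×100 px that follow the core's edge
   and are clipped to the breast mask (tiles near the contour may be
   shorter). For each tile pair (a tile and its mirror across the core)
   the per-column mean intensities are computed; the baseline is the
   straight line through the *minimum* column mean on the illuminated
   side and the *maximum* column mean on the darkened side. Subtracting
   `mean − baseline` from every pixel of a column flattens the ramp while
   preserving within-column structure. Which side is "illuminated" is
   decided by comparing mean intensity in the band-adjacent tiles.
5. **Contrast equalization** (`side_stats`, `adaptive_clip_limit`,
   `equalize_low_contrast_side`). The in-mask, non-core pixels are split
   by the core's column span; each side's histogram mode and population
   standard deviation are computed. Side A is the higher-variance
   (uncorrupted) side, B the degraded one. CLAHE with an 8×8 tile grid is
   applied to B's bounding box with the clip limit

   `clip_limit = 1.11 − 0.023 · (stdB − stdA)`,

   an empirical linear model relating the optimal clip limit to the
   contrast gap. Because the line can turn non-positive for large gaps
   and CLAHE needs a positive limit, the value is floored at 0.1. The
   equalized side is blended back with a 20-column linear feather at the
   core boundary so no seam appears; the A side is left bit-identical. A
   constant (zero-variance) side is returned unchanged with a warning —
   there is nothing to equalize. Note that at clip limits near 1.1 CLAHE
   is intentionally gentle; it narrows, but does not close, the contrast
   gap.
6. **Core restoration** (`interpolate_core`, `restore_background`,
   `streak_mask`, `overlay_streaks`). Two complementary restorations are
   fused:
   * *Interpolation* fills each core row with a degree-1 polynomial
     through anchors placed on the columns adjacent to the interval, each
     anchor value the mean of the 3 nearest flank columns (averaging
     resists pixel noise). This carries linear structures that cross the
     band — vessels, fibrous strands — across the gap, but smears the
     background and paints horizontal noise bridges. Higher degrees are
     supported and change little while amplifying noise.
   * *Background inpainting* fills the core with a smooth field. The
     restorer is a pluggable contract (`function(img, hole)`, validated
     to touch only the hole) so a neural inpainter can be dropped in; the
     default `restorer_biharmonic()` minimizes the squared discrete
     Laplacian over the hole, continuing both intensity and gradient
     across the boundary. `restorer_diffusion()` (harmonic fill) and
     `restorer_coarse_fine()` (downsample–inpaint–upsample for very
     large holes) are alternatives. All reconstruct background, not
     texture or streaks.
   * The *streak mask* decides which pixels keep the interpolated value:
     CLAHE with a deliberately large clip limit (20) over the
     core-plus-margin window (50 columns each side), then a global
     binarization at two-thirds of maximum brightness — boosted pixels
     strictly above 170 are "informative". The composite takes
     interpolated values at masked core pixels and inpainted values
     elsewhere, so every composite pixel comes verbatim from one of its
     two sources.

If no core is detected, the restoration stages are bypassed: side
statistics are taken about the median in-breast column, the low-contrast
side is still equalized, and the composite is that equalized image with an
empty streak mask.

## Evaluation machinery

* `compute_ssim` — single-scale structural similarity, 11×11 Gaussian
  window with σ = 1.5, stabilizers `(0.01·255)²` and `(0.03·255)²`,
  statistics over the valid region only. `compute_gmsd` — gradient
  magnitude similarity deviation: 2×2 block-mean reduction, Prewitt
  gradients over the valid region, similarity constant 170, population
  standard deviation of the similarity map. Both are verified in the
  test suite against frozen values from an independently written
  reference implementation; identities (SSIM = 1, GMSD = 0 on
  self-comparison) hold exactly.
* `metric_report` arranges scores as a table (metric × method) with a
  better-is direction per row; additional scorers — including
  no-reference ones such as BRISQUE or NIQE — attach as plugins and a
  failing plugin yields an `NA` row rather than an error.
* `strip_experiment` cuts a 5-pixel vertical strip from a defect-free
  image (complete, localized information loss, no detection needed),
  restores it by interpolation alone, inpainting alone and the overlay,
  and scores each against the uncut original over the whole image.
* `first_order_features` computes the 18 standard first-order radiomics
  descriptors with fixed-bin-width 25 discretization for
  entropy/uniformity (bins anchored at the region minimum); pixels have
  unit area, so total energy equals energy. Skewness and kurtosis of a
  constant region are reported as 0. Texture features enter through a
  pluggable extractor in `build_feature_table`.
* `anova_oneway` (classical equal-variance F test via
  `stats::oneway.test`) and `tukey_hsd` (studentized-range statistic
  `Q = |x̄_i − x̄_j| / √(s²_w/n)` with the pooled within-group mean
  square, p-values from `stats::ptukey`) feed `feature_drift_report`,
  which counts, per restoration method, the percentage of features whose
  ANOVA and original-vs-method Tukey comparison are both significant at
  0.05. The Q formula assumes balanced groups and the implementation
  enforces that; the within-group dispersion is interpreted as the pooled
  within-group mean square, the standard Tukey HSD choice.

## The phantom generator

No clinical images ship with the package, so `generate_phantom` emulates
the morphology the pipeline relies on: a half-elliptical breast flush
with the left image edge (~52% of the frame) on true-black background;
tissue intensity = background level 120 + a smooth Gaussian texture field
(smoothing radius 6 px, sd 8) + fine pixelwise detector noise (sd 3);
and 8 bright curvilinear streaks (Bézier arcs, Gaussian cross-profile
σ ≈ 1–1.8 px, peak ~40 above background) that radiate across the image
width, as ducts and vessels run toward the nipple and therefore cross a
vertical band transversally. Every draw comes from a private RNG stream
seeded by the spec, so phantoms are bit-reproducible and never disturb
the global RNG. The generated image carries its ground truth (breast
mask, streak raster, streak-free background) as attributes.

`inject_band_defect` adds the defect: additive gain inside the band
(saturating at 255 when gain = 255), raised-cosine flank ramps (default
amplitude 60 bright / 30 dark over 150 columns — the defect's flank
extent and ramp shape are not standardized anywhere, so they are exposed
as parameters), and a multiplicative contrast reduction of the dark side
about its mean. `cut_strip` zeroes a known column interval for the strip
benchmark.

What the phantom does **not** emulate: real parenchymal texture (whose
fine-scale amplitude is much higher than the phantom's smooth field),
skin line and pectoral muscle, scatter, lesions, and the resolution of a
clinical detector (a 5-px strip on a 512² phantom is relatively far wider,
compared with the tissue correlation length, than on a native ~4000×5500
mammogram). Consequences: a passing suite shows the pipeline's mechanics
are correct — detection, flattening, equalization, fusion, statistics —
not that restored clinical images are diagnostically adequate. One
consequence is measurable here: with a competent classical inpainter a
5-px hole is bridged nearly optimally by inpainting and by per-row
interpolation alike, so the three restorations differ by ~10⁻⁴ SSIM on
the phantom and the fused overlay wins the strip benchmark in only about
half of the seeds rather than dominating as it does on clinical tissue,
where interpolation's horizontal noise bridges and a learned restorer's
soft streaks give the fusion clear, complementary gains. With the
phantom's ground-truth streak raster substituted for the computed mask,
the overlay dominates in every seed — the fusion logic is sound, and the
gap is the specificity of the fixed clip-20/threshold-171 binarization on
synthetic texture.

## Numerical conventions

* Rounding is half-up (`floor(x + 0.5)`) everywhere an intensity is
  written back; results are platform-reproducible.
* Histogram-mode ties break toward the smallest intensity; side-label
  ties (equal standard deviations) label the left side A.
* Standard deviations are population (divide-by-N) statistics.
* CLAHE follows the Zuiderveld tile-grid algorithm (via EBImage); inputs
  are padded by edge replication to tile-divisible sizes and cropped
  back, and a window too small for a 2×2 grid — or a constant window,
  which carries no streak information — passes through untouched.
* The biharmonic solve is restricted to the hole dilated by two pixels,
  outside of which the solution provably does not depend on the data.
* Degenerate inputs: empty cores propagate as the bypass path;
  zero-width strips are identities; an interval touching the image edge
  is extended as a constant from the available side.

## Problem sizes

The shipped tests exercise 512×512 phantoms (20 seeds for the strip
benchmark and the detection-recovery study), 10,000 replicates for the
ANOVA type-I calibration, and one full-resolution (4052×5539) I/O round
trip — sizes chosen so the whole suite completes in about a minute while
every statistical bound retains adequate Monte-Carlo resolution.
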