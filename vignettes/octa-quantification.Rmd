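---
title: "Quantifying en-face OCTA scans: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying en-face OCTA scans: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaquant)
```

## What the package computes

Optical coherence tomography angiography (OCTA) produces depth-resolved
en-face maps of retinal blood flow. For a 3 x 3 mm macular scan sampled
at 245 x 245 pixels, octaquant quantifies three slabs - the superficial
capillary plexus (SCP), the deep capillary plexus (DCP) and the
choriocapillaris (CC) - into nine per-eye outcomes: perfusion density
(PD) of the SCP with and without large vessels (LV), LV perfusion
density, PD of the DCP, area and circularity of the foveal avascular
zone (FAZ) in both plexuses, and the CC flow-deficit percentage. The
cohort layer compares these outcomes between an MS group and a control
group with linear generalized estimating equations (GEE) that account
for the correlation between the two eyes of one participant.

The per-eye pipeline is:

1. The FAZ boundary of each plexus is an input polygon (in clinical
   practice it is traced by a grader; the synthetic generator stands in
   for the grader here).
2. LV on the SCP are enhanced by an oriented even-Gabor filter bank
   combined with a multiscale Hessian (Frangi) vesselness filter and
   binarized.
3. Each plexus is binarized at its mean intensity (`>=` keeps ties, so
   a constant image is all vessel), and the FAZ region is masked out.
4. LV artifacts are removed from the CC angiogram and flow voids are
   pixels strictly below mean minus one sample SD of the remaining
   pixels.
5. All densities are measured inside a fovea-centered annulus (inner
   diameter 1.0 mm, outer 2.5 mm). The annulus is rescaled per eye with
   Bennett's formula, `s_actual = p * q * s` with
   `q = 0.01306 * (axial length - 1.82)`, so that the *physical* region
   of measurement is the same for every eye. The instrument's camera
   factor `p` is not published; the default `p = 3.382` makes a
   24.46 mm (nominally emmetropic) eye magnification-neutral, and the
   parameter is configurable. The annulus is rescaled; the image is
   never resampled.
6. FAZ area (shoelace formula, converted by the eye-specific pixel
   scale) and circularity `P / (2 * sqrt(pi * A))` are computed on the
   annotation polygon, not on a raster mask - raster boundaries
   systematically overestimate perimeters.

## Parameters that matter

* **Enhancement bank.** Gabor wavelengths {8, 12, 16} px, 8
  orientations, Hessian scales {3, 5, 7} px: trunk vessels in a 3-mm
  scan at 245-px sampling are roughly 4-10 px wide. The two responses
  are min-max normalized and multiplied (agreement between an oriented
  and a tubular detector), thresholded at the mean of the combined
  response. Because large vessels carry the strongest flow signal, the
  candidate map is intersected with the upper Otsu class of the
  vessel-pixel intensities, then opened with a disc of the minimum
  trunk caliber (5 px) and filtered at a 100 px minimum component size,
  which keeps capillary-scale texture out of the LV map.
* **Vessel-removal halo (8 px, about 0.1 mm).** The without-LV density
  removes the dilated LV map from the numerator only. The halo default
  is derived from the published density decomposition itself: with
  total SCP PD near 42%, LV PD near 6.7% and without-LV PD near 29%,
  the excluded perivascular band must hold the remaining ~6-7
  percentage points of capillary signal at the ambient capillary
  density, which implies an exclusion band of roughly 8 px around a
  5-6 px trunk - an anatomically plausible periarteriolar
  capillary-free zone. The same halo masks LV artifacts in the CC. The
  radius is a single configurable parameter (`lv_removal_dilate_px`).
* **Thresholds.** Plexus binarization uses the whole-image mean (the
  source procedure states the mean of the respective image without
  restricting the support); CC statistics are computed over non-excluded
  pixels only, because artifact removal precedes thresholding. The
  sample SD is used; at 60,025 pixels the population/sample distinction
  is far below every reported precision.

## The synthetic cohort: what it emulates

No raw scans are publicly deposited, so validation runs on synthetic
eyes whose ground truth is exact by construction:

* **Capillary texture** is the set of nodal bands of a band-pass
  Gaussian random field: pixels where the field magnitude falls below
  the quantile that yields the requested density. This gives a thin
  (~2 px), connected, plexus-like mesh whose density is controllable to
  one pixel at any value in [0, 1] - the reason this construction was
  chosen over thresholding-plus-skeletonization, which does not offer
  exact density control. Capillary strokes are rendered at a fixed
  level (170) over background (60) with additive noise (SD 10), so the
  mean-intensity threshold sits many noise SDs from both modes and the
  binarizer re-detects the truth mask essentially exactly.
* **Trunk vessels** are random smooth strokes entering from the image
  edge, steered away from the fovea, drawn at caliber 5 px and level
  230 (LV are brighter than capillaries in real angiograms; the
  brightness separation is also what the Otsu refinement exploits).
  Three strokes per eye give an annulus LV density of about 6.3 +/- 1.4%,
  matching the published ~6.6%. The SCP realizes two density targets at
  once: the without-LV density outside the halo and the total density,
  by placing the balance of capillary pixels inside the perivascular
  ring.
* **FAZ outlines** are star-shaped polygons `r(theta) = R (1 + a g(theta))`
  with a smooth random harmonic profile g (orders 2-8). The polygon is
  rescaled to the exact target area; the amplitude `a` is solved by
  root-finding when a target circularity is requested (tolerance 1e-3).
* **CC texture** is a two-level granular field whose low level occupies
  exactly the requested deficit fraction of the annulus; the two levels
  are placed so the image matches the requested mean and SD. The
  mean-minus-SD threshold then falls between the levels, which holds
  for deficit fractions up to roughly 0.3 - well beyond the ~16%
  physiological range simulated here.
* **Cohort structure.** Group sizes default to the published design (58
  MS participants/100 eyes, 78 controls/136 eyes; every participant
  gets two eyes and random participants are demoted to one eye until
  the totals match). Outcome ground truths are drawn per eye around a
  participant-level random effect with inter-eye correlation `rho`
  (default 0.7, a typical inter-eye value for perfusion metrics);
  right-skewed outcomes (FAZ areas, circularity minus one) use
  moment-matched lognormals so that means are unbiased despite the
  physical bounds. By default each group's drawn values are recentred
  so the realized group mean equals the configured mean exactly
  (`exact_group_means`): the generator's job is to realize the
  configured study conditions, and recentring removes only the
  cohort-level sampling wander while leaving SDs and the correlation
  structure intact. Covariates (age, gender, IOP, axial length,
  hypertension, signal strength) follow the published cohort
  characteristics; hypertension prevalence (10% control / 15% MS), MS
  duration (Gamma, mean 8 y) and episode count (1 + Poisson(2)) are not
  published and were fixed once at clinically plausible values. Axial
  length uses SD 0.9 mm - the published "+/- 0.1" is read as a standard
  error, since a 0.1 mm population SD of axial length is not
  physiological.

What the generator does *not* emulate: speckle, projection artifacts,
motion artifacts, segmentation errors, or optic-neuritis eyes. Passing
the round-trip tests therefore shows that the measurement pipeline is
unbiased for clean, well-separated angiograms - not that it is robust
to the full artifact spectrum of clinical OCTA.

## Cohort statistics

Participant characteristics are compared with a Shapiro-Wilk-gated
choice (per group, alpha 0.05) between the equal-variance t-test and
Kruskal-Wallis; categorical variables use chi-square, switching to
Fisher's exact test when any expected cell is below 5.

Outcomes are modelled per eye with a linear GEE: identity link,
exchangeable working correlation (the natural choice for at most two
eyes), clusters = participants, robust sandwich covariance, Wald tests
on the group coefficient. The point estimates and the plain Liang-Zeger
sandwich agree with the statsmodels reference to ~1e-6; for inference
the package uses the Mancl-DeRouen bias-corrected sandwich with t
quantiles on clusters-minus-parameters degrees of freedom, because the
plain sandwich is anti-conservative at realistic cluster counts
(simulated type-I error 0.07 and CI coverage 88% at ~30 clusters,
versus 0.05 and 94% with the correction). Adjusted means are
marginal predictions with covariates at grand sample means (proportions
for categorical covariates); the adjustment set is age, gender,
hypertension and OCTA signal strength, plus any candidate (IOP, axial
length) with univariate GEE P < 0.10. Unadjusted means come from an
intercept-plus-group GEE so their SEs are cluster-robust too. No
multiple-testing correction is applied across the nine outcomes,
mirroring the reporting convention of the source study. Associations
with MS duration and episode count are univariate GEEs on MS eyes only.

## Numerical conventions and degenerate inputs

* Pixel coordinates are 0-based, x rightward, y downward; matrices are
  indexed `[y + 1, x + 1]`. Polygon rasterization uses the
  pixel-center-inside, even-odd scanline rule with a half-open edge
  convention, so vertices on scanlines are not double-counted.
* Constant images: plexus binarization keeps ties (all vessel);
  flow-void binarization uses a strict inequality (no voids).
* Self-intersecting polygons, empty annuli, out-of-range axial lengths
  (outside 20-30 mm), an LV mask covering the whole CC image, and
  cohort configurations with more than two eyes per participant are
  rejected with explicit errors.
* Determinism: every random step is seeded; a master seed spawns
  per-eye seeds by a fixed counter scheme, so identical configurations
  give byte-identical cohorts, and re-measuring a cohort is exactly
  reproducible.

## Problem sizes used in the test suite

The validation suite runs the full published design once (236 eyes,
generate + measure + analyze) for the round-trip recovery check, and
uses 300-replicate truth-table simulations at 30 + 30 eyes for type-I
error and CI coverage of the GEE layer; under a no-group-effect null
the image-measurement step is group-blind, so simulating the truth
tables directly exercises the statistical property at meaningful
replicate counts. Unit tests run on small grids (16-245 px) with
brute-force counting oracles.

## Known limitations

* The camera factor `p` of the source instrument is unpublished;
  absolute FAZ areas and annulus scaling are exactly reproducible only
  up to this calibration constant.
* LV segmentation accuracy is validated against the synthetic trunk
  model (Dice >= 0.99 there); clinical angiograms with lower contrast
  between trunks and capillaries will degrade gracefully but are not
  covered by these tests.
* The published decomposition of SCP density into with/without-LV rows
  is not additive; the 8 px halo default reconciles it, but the true
  halo used originally is unknown and the parameter should be treated
  as tunable when matching other datasets.
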