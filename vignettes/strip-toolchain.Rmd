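---
title: "From test-strip photo to chlorine tier: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From test-strip photo to chlorine tier: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorosnap)
```

## The problem

Free chlorine residual — the dissolved hypochlorous acid/hypochlorite left
in treated drinking water — is the main barrier against pathogen regrowth
between the treatment plant and the tap. Utilities care most about three
regulatory bands: below 0.2 mg/L (reportable, potentially unsafe), 0.2–0.5
mg/L (marginal), and above 0.5 mg/L (comfortable). DPD test strips are
cheap and ubiquitous, but reading them by eye is unreliable: the magenta
color change between adjacent concentrations is small, and ambient lighting
shifts the apparent hue.

chlorosnap implements an automated reading chain. A strip is photographed
on a *standard background* — a printed card with a black rectangle about
three strip-widths wide (so placement need not be exact) and a QR-like
fiducial. The photo is color-corrected, geometrically rectified, the
colorimetric pads are located, their mean RGB is extracted, a regression
calibration converts color to concentration, and the concentration is
binned into a tier. Because no photographic dataset ships with the package,
a seeded synthetic scene renderer stands in for the camera: every stage is
tested against rendered scenes with exact ground truth.

## The processing chain

1. **Gray-world balance (whole photo).** Assuming the scene's average color
   is achromatic, each channel is rescaled by `(Gray/3)/channel_mean`,
   where `Gray` is the sum of the three channel means. For a lighting cast
   that acts as a diagonal channel gain, this removes the cast up to a
   single global scalar. The transform is idempotent and commutes with
   pixel permutation — both properties are asserted in the tests.
2. **Fiducial detection.** The fiducial carries three nested-square finder
   patterns. After Gaussian blur and Otsu thresholding, a finder is
   recognized by its nested-contour signature: a dark square ring whose
   bounding box is roughly square, with a separate concentric dark core.
   The three ring centroids (sub-pixel accurate by symmetry) plus the
   inferred fourth corner form the fiducial quad. Detection never raises on
   bad content; it returns a typed failure that batch reports tally by
   stage.
3. **Perspective alignment** is coarse-to-fine. The coarse homography maps
   the detected quad onto its nominal position in the base layout and
   warps the photo onto the base canvas (bilinear sampling). Using the
   finder *centroids* rather than edge-derived points matters here:
   thresholded edges carry a systematic half-pixel bias under blur, while
   centroids of symmetric shapes do not. Because the quad's fourth corner
   is inferred by parallelogram completion, the coarse transform is affine
   and leaves a perspective residual of 10–20 px at the far edge of the
   card under an 8° tilt; a refinement pass therefore detects the black
   rectangle in the coarse result and re-estimates the homography
   (least-squares, normalized DLT) from the three finder centers plus the
   rectangle corners against their nominal positions, which brings the
   whole card within ~2 px of its nominal geometry.
4. **Black rectangle and strip.** Dark components are gated on
   height/width aspect and area; the largest survivor wins; corners are the
   component's extreme pixels along the two diagonal directions (robust to
   small residual rotation). The strip is the largest bright component
   inside the rectangle, gated on its elongation.
5. **White-reference balance (strip crop).** Pixels whose minimum channel
   is at least 200 are "white" (the strip's body qualifies; colored pads do
   not). The crop is rescaled per channel by `255/white_mean`, mapping the
   white body to (255, 255, 255). The literal-reciprocal variant
   (`white_mean/255`) is available behind `pipeline_config(wb_variant =
   "reciprocal")` because the two forms both appear in informal
   descriptions of white-patch correction; the gain form is the standard
   one and the default.
6. **Pads and extraction.** The total-chlorine pad sits near the strip's
   top end (fraction 0.10 of the strip length), the free-chlorine pad
   mid-strip (0.45) — both config-exposed since only relative placement is
   fixed. The pad polygon is shrunk to 75% of the nominal pad so that the
   inscribed circle — centered at the polygon centroid, radius the minimum
   centroid-to-edge distance — tolerates a few pixels of localization
   error. The mean RGB is taken over pixels whose centers fall strictly
   inside the circle (boundary ties excluded, for reproducible integer
   geometry).
7. **Calibration and binning.** Three regression families are provided:
   concentration on the RGB sum, on (R, G), and on (R, G, B, R², G², B²).
   Backward stepwise selection greedily removes the single term whose
   removal most lowers AIC and stops when none does; the intercept is never
   dropped. Predictions are *not* clamped: a zero-chlorine strip can
   legitimately regress slightly negative, and the binning stage sends any
   negative value to the lowest tier.

The published coefficient sets ship as `published_model()` (selectable as
`"paper-2022"` from the CLI). They were fit to the original photographic
data, so they are not expected to be accurate on synthetic scenes —
synthetic runs train their own calibration. In the printed polynomial the
x1/x2/x3 symbols are never explicitly bound to channels; the package
assumes the conventional R, G, B order (matching the two-channel model,
where the assignment is stated) and records that assumption in the model's
`channel_assignment` field.

## The synthetic scene model

The renderer emulates the capture conditions the chain must survive:

* **Pad color.** Channel anchors are interpolated linearly in
  concentration and constrained to per-tier channel boxes (the observed
  min/max of each channel within each tier: R 122–193, 133–182, 98–170; G
  125–193, 111–170, 57–146; B 135–179, 128–175, 114–170 for the three
  tiers in order). Anchors were chosen once so each tier's interior anchor
  sits at the midpoint of its box and the RGB sum is strictly decreasing
  over 0–4 mg/L, mirroring the negative sum–concentration relationship
  that motivates the linear calibration. Pad-to-pad variability is
  Gaussian with sd 6 color values, truncated to the tier box — roughly a
  sixth of a typical box width, a realistic strip-to-strip spread.
* **Lighting casts** are diagonal channel gains (warm: R ×1.2, B ×0.85;
  cool: mirrored). A cast is exactly the error model that the two-stage
  balance is designed to remove, so post-balance pad colors agreeing
  across casts (the tests require ±5 per channel; in practice they agree
  within ±0.5) is a meaningful end-to-end check of the balancing chain.
* **Resolution levels** scale the long edge to 260/520/640 pixels —
  proportional to the square roots of 2, 8 and 12 MP, the sensor classes
  of interest — via Gaussian anti-alias filtering and area downsampling.
  Low resolution smears the one-module gap between a finder's ring and
  core, so fiducial detection fails much more often there, reproducing the
  direction (not the numbers, which are data-bound) of the reported
  failure accounting.
* **Tilt** is a pinhole-model rotation about the vertical axis (focal
  length 1.8 × width), safe up to ±10°.
* **Paper white is rendered at 210**, not 255, so a 20% cast gain cannot
  clip it: clipping would destroy the information the white reference
  needs and is precisely what a camera's auto-exposure avoids. A
  consequence is that Eq-style white referencing rescales all extracted
  colors by 255/210 ≈ 1.21. Ground truth therefore carries the pad color
  in both capture space (`pad_rgb_free`) and white-referenced space
  (`pad_rgb_free_ref`); end-to-end color-recovery tests assert in the
  referenced space, pre-balance tests in capture space.
* **The canvas is mid-gray**, so the gray-world assumption is neither
  trivially satisfied nor pathologically violated.

What the renderer does **not** model: vignetting and shadow gradients,
glare, chromatic camera response curves, defocus, JPEG artifacts, or real
DPD chemistry (interferents, timing effects). Passing tests demonstrate
that the chain is correct under controlled geometry/illumination/noise;
they do not certify performance on arbitrary field photos.

## Statistical conventions

* **Tiers.** Boundaries are half-open on the left (`a < C <= b`), matching
  the concentration-group convention; 0.5 mg/L itself is in the positive
  (≤ 0.5) class. Negative predictions map to the lowest bin.
* **Confusion matrices** are rows = predicted, columns = true, the printed
  orientation. Metrics: accuracy, per-class precision/recall/F1, weighted
  F1 (support-weighted), micro F1 (pooled; equals accuracy for single-label
  classification — asserted over random matrices). Zero-denominator
  per-class metrics are reported as 0 with a warning. Reported percentages
  round half-up to a whole percent.
* **Stratified splitting** allocates `round(fraction × n)` training rows
  across groups by largest remainder, which reproduces the reference
  photo-count table exactly (e.g. 21, 27, 54, 36, 46, 8 photos at 67% →
  14, 18, 36, 24, 31, 6). Resampled validation repeats split–fit–score and
  reports each metric's mean and spread.
* **Proportion comparison.** The pooled two-proportion z-test covers the
  two-group case. With three phone or lighting groups, a single pairwise
  z-test cannot summarize the comparison, so `proportion_tests()` reports
  all pairwise tests plus an overall chi-square; the package does not claim
  to reproduce any single printed p-value for three-group comparisons.
* **AIC stepwise.** AIC is the Gaussian-likelihood form via `stats::AIC`;
  greedy backward, one term per iteration. A caveat worth knowing: with
  AIC's fixed penalty of 2, a truly null term survives backward
  elimination with probability ≈ P(χ²₁ > 2) ≈ 0.16, so on data generated
  without blue-channel effects both blue terms are pruned in only ~70% of
  replicates. That is a property of AIC selection itself, not of this
  implementation (which matches `stats::step` exactly on shared inputs).
* **Bayes sequence cases.** The source data motivating the conditional
  probability analysis do not pin down the prior over true classes or the
  dependence among repeated samples, and the printed "0.14 (10/74)"
  likelihood is inconsistent with the printed combined matrix (2/66 in the
  stated orientation; 11/75 transposed). The package fixes one explicit
  model — shared unknown true class, empirical true-class marginal prior,
  conditionally independent classifications — and supports both matrix
  orientations behind a flag. Case probabilities computed under this model
  are reported, not asserted against the printed bounds.

## Numerical choices

Balancing arithmetic is in doubles, clipped to [0, 255] after each
balance, rounded only on image write. Otsu thresholds are computed on
256-bin histograms with config overrides. Homographies come from the exact
4-point linear solve; degenerate (collinear) quads raise. Circle membership
is strict (`distance < r`). Degenerate fits (rank-deficient designs,
all-zero residuals) raise typed errors or set a `degenerate` flag rather
than silently pseudo-inverting.

## Problem sizes

The test suite and the acceptance script use a 120-scene battery (the six
concentration groups in reference proportions, all three casts, mid/high
resolution, |tilt| ≤ 8°, pixel noise sd 3) for end-to-end training, a
30-scene high-resolution battery plus a 16-scene low-resolution battery
for geometry, and n = 500 rows × 20 seeds for stepwise-selection
behavior. On one CPU the full suite runs in a few minutes.

## Worked example

```{r example, eval = FALSE}
library(chlorosnap)

dir <- tempfile("scenes")
manifest <- make_dataset(120, dir, seed = 1)
fit <- train_toolchain(manifest, dir, family = "polynomial_sq", seed = 2)

fit$metrics$binary$accuracy      # held-out binary accuracy
fit$metrics$multiclass$weighted_f1
glance(fit$model)                # adjusted R^2, AIC of the calibration

# classify one new photo
sc <- render_scene(scene_spec(0.35, "warm", "high", 5, 3, seed = 9))
process_photo(sc$image, model = fit$model)
```

## Known limitations

* The renderer's casts are global and diagonal; real illumination fields
  (shadows, vignetting) are out of scope, as are HSV/Lab color spaces.
* Only one strip per photo is supported, and the fiducial payload is never
  decoded — only its geometry is used.
* The published calibrations transfer poorly to any data not drawn from
  the original capture conditions; they are included for evaluating the
  machinery, not for field prediction.
* Fiducial detection tolerances were set by what is testable on synthetic
  scenes, not by matching any external implementation.
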