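---
title: "Methods: two-stage quantitative vertebral morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage quantitative vertebral morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertemorph)
```

## The measurement problem

Quantitative morphometry (QM) grades vertebral body deformity on a lateral
radiograph from six landmarks per vertebra: the upper and lower points of
the anterior, central and posterior edges (AU/AL, CU/CL, PU/PL). The
anterior, central and posterior heights are the Euclidean distances between
the paired points, and deformity is summarised by the height ratios C/A,
C/P and A/P. Wedge deformity depresses A/P, biconcave deformity depresses
C/P, and crush deformity lowers all three heights together. Automating QM
requires (i) finding each vertebral body on the radiograph and (ii) placing
the six landmarks on it; this package implements both stages with pluggable
detection/landmark backends, plus the statistics used to judge agreement
with human annotators.

Coordinates are pixels, 0-based, origin top-left, x rightward and y downward
(cranio-caudal). The anterior side defaults to the left image edge
(`anterior_side` in `phantom_spec()`); radiograph laterality varies between
archives, so the flag is explicit rather than assumed. Height ratios are
unit-free, so pixel spacing is carried as metadata only.

## Stage 1: detection and spinal-curve filtering

`segment_vertebrae()` produces instance masks. The reference backend —
global Otsu threshold plus connected-component labelling, small components
below `min_area = 20` px discarded — is deterministic and adequate for
phantom images where bone is brighter than background; a learned instance
segmenter can be dropped in as any function `image -> mask table`. Each
mask is reduced to its center of gravity (`mask_centroid()`), the unweighted
mean of foreground pixel coordinates: the centroid is a property of the
binary segmentation, not of image intensities.

False detections (diaphragm edges, airway walls, ribs) rarely sit on the
spine. `fit_spinal_curve()` therefore fits x = f(y), a polynomial of degree
1–4, to all centers with RANSAC, and `filter_centers()` keeps the inliers.
Parameterizing on y makes a vertically running spine single-valued; x = f(y)
would fail only for rotated images, which are out of scope.

Numerical choices in the RANSAC fit:

* **Minimal samples** of size degree + 1 per candidate degree; every degree
  from 1 to min(4, n − 1) is searched. When a degree has no more than
  `n_iter` (default 500) minimal samples, all of them are enumerated, making
  the search exhaustive — and independent of the seed — for typical
  per-image center counts. Otherwise `n_iter` seeded samples are drawn.
* **Model selection**: most inliers, ties broken by lower degree, then by
  lower sum of squared inlier residuals. The lower-degree tie-break prevents
  quartics from chasing centroid quantisation noise.
* **Refit and re-flag**: each degree's best consensus is refit by least
  squares on its inliers, and inlier flags are recomputed against the refit
  model until a fixpoint (at most 25 rounds). This guarantees the reported
  invariant — every flagged inlier is within `residual_threshold` of the
  reported coefficients — and demotes minimal-sample models that over-reach:
  a line through two lucky centers may capture a gently curved spine within
  a generous threshold, but its least-squares refit cannot hold that
  consensus, while the quadratic can. Degrees then compete on their
  post-refit inlier counts.
* **`residual_threshold`** defaults to 0.5 × the median nearest-neighbour
  spacing of the centers. "Deviating significantly" has no canonical pixel
  value; half the intervertebral spacing is scale-free across image
  resolutions and separates off-spine structures (typically several spacings
  away) from on-spine centers (well under half a spacing after a sane fit).
  It is a declared default, exposed as a parameter.
* Degenerate samples (duplicate y) are skipped; if every sample is
  degenerate the fit raises a classed error rather than returning nonsense.

`crop_vertebra()` extracts a side × side window (default 224 px, the input
size of common CNN backbones) anchored at integer pixels: the origin is
`round(center) − side %/% 2`, so the affine crop↔image map is an exact
integer translation and round-trips to machine precision. Out-of-image
regions are padded with the image median (the background level on a
radiograph-like histogram) and the padding per edge is recorded.

## Stage 2: landmarks and morphometry

`predict_landmarks()` accepts any backend `(crop, window) -> ` the 12 named
coordinates in crop pixels; outputs are validated (finite, inside the crop)
and mapped back with `to_image_coords()`. The shipped backend is a truth
oracle for phantoms (`landmark_backend_oracle()`) that perturbs the ground
truth with zero-mean Gaussian noise of configurable SD. Noise is drawn from
a per-vertebra seed derived from the backend seed, which has two useful
consequences: repeated predictions on the same crop are identical, and runs
at different noise SDs with the same seed use *common random numbers* — the
landmark displacement scales exactly linearly with the SD, so
noise-degradation studies are monotone by construction rather than by luck.
Crop-pixel coordinates (not [0, 1]-normalised) are the regression target
convention fixed by the interface.

`vertebra_morphometry()` appends heights, ratios, collapse percent and QM
bin to a landmark table. Collapse percent is defined as
100 × (1 − min(A/P, C/P)), floored at 0: the worst proportional anterior or
central loss relative to the posterior edge. The defining categories are
cited from prior work without a printed formula, so this within-vertebra
definition is the package's own; it sees wedge and biconcave deformity but
is blind to pure crush, for which an optional `crush_reference` mode
compares each posterior height against the mean of its cranial/caudal
neighbours (off by default — the caudal size gradient of a normal spine
already produces ~3 % pseudo-loss under this mode, so it is a screening
aid, not a measurement).

QM bins are half-open: [0, 20) → "<20", [20, 25) → "20–25",
[25, 40) → "25–40", [40, ∞) → ">40". The printed bin labels overlap at
their boundaries; sending boundary values upward is this package's
documented convention. Note that a constructed severity of exactly 0.40 can
land a floating-point hair below 40 % after the height arithmetic and bin
as "25–40"; the bin is always consistent with the computed value under the
stated convention.

The review flag (`flag_discrepancy()`) marks vertebrae with any
|Δratio| ≥ 0.2 between two measurements, the threshold used to surface gross
annotation failures (landmarks on an adjacent vertebra, facet or diaphragm).
The comparison is inclusive, with a 1e-9 slack so that a difference
constructed to be exactly 0.2 is not lost to float rounding.

## Agreement statistics

* `match_detections()`: greedy one-to-one matching in increasing distance
  order; a prediction is TP iff matched within `tau`. The TP criterion for
  detection has no canonical definition; the default `tau` is half the local
  reference vertebral height, which is scale-free and, for spine-like
  geometries (references separated by more than one vertebral height),
  provably equivalent to the optimal assignment. `detection_metrics()`
  reports sensitivity TP/reference, precision TP/(TP+FP) and FP per image as
  exact quotients; an FP count of 79 over 188 images is reported as
  0.4202..., not pre-rounded.
* `landmark_errors()`: per landmark and axis, |Δx| as a percent of the
  reference vertebra's width and |Δy| of its height, where width is the mean
  of the upper and lower edge spans and height the mean of the anterior and
  posterior heights. "Width and height" of an irregular hexagon admits
  several definitions; the mean-of-edges choice is symmetric under the
  deformity types and documented here. It affects the percentages, never
  the coordinates.
* `qm_correlation()`: Shapiro–Wilk on each series gates Pearson
  (both p ≥ 0.05) versus Spearman. The gate level 0.05 matches the
  conventional significance threshold. Shapiro–Wilk is defined for
  n ≤ 5000; longer series are gated on a deterministic evenly-spaced
  subsample of 5000. Coefficients and p-values come from `stats::cor.test`,
  including its exact small-sample Spearman handling.
* `bland_altman()`: differences are algorithm − reference, MD ± 1.96 sample
  SD gives the limits of agreement (the interval expected to cover 95 % of
  differences under normality), and proportional bias is the OLS regression
  of differences on pair means (slope, p, R²). Subgroup rows per QM bin
  report n, MD ± SD and the percentage of that bin's pairs inside the
  *global* LOA — one LOA per ratio, so that increasing per-bin exclusion
  directly shows severity-dependent disagreement. Zero-variance differences
  collapse the LOA to [MD, MD] and mark the trend undefined rather than
  erroring.

## The phantom: what it emulates, and what it does not

`generate_phantom()` renders a vertically running column of vertebra-like
bodies whose centers lie exactly on a degree ≤ 4 polynomial x = f(y)
(default: a quadratic bow with 12 % of the image width of end deflection,
a mild sagittal curve). Each body is a filled hexagon whose boundary passes
exactly through its six landmarks, so truth annotations and rendered shape
agree by construction; `truth_morphometry` is literally
`vertebra_morphometry(truth_landmarks)`. Defaults: 14 vertebrae (T4–L5),
512 × 256 px, base 40 × 22 px growing 3 % per caudal level (lumbar bodies
are larger than thoracic), 8 px gaps, bone 0.75 vs background 0.25 gray,
0.7 px Gaussian edge smoothing, additive noise SD 0.02 — a schematic but
plausibly proportioned spine at desk scale.

Deformity severity s maps directly onto the defining ratio: wedge sets
A/P = 1 − s (with a straight superior endplate, so C/P = 1 − s/2),
biconcave sets C/P = 1 − s, crush scales all heights by 1 − s. No published
geometric parameterization of deformity subtypes exists at this level of
abstraction; this mapping is a declared stand-in chosen so that requested
severity and measured collapse percent coincide by construction, which is
what makes severity-recovery tests exact. Confuser structures — a diaphragm
dome low in the anterior field, a posterior airway wall, an oblique rib
crossing a vertebral margin — are bright curvilinear edges reproducing the
classic false-positive sources.

What the phantom does *not* emulate: projection physics, exposure and
scatter, cortical/trabecular texture, endplate curvature, osteophytes,
overlapping anatomy, scoliosis (multi-valued x(y) is out of scope), or
inter-annotator ambiguity in landmark placement. Passing phantom tests
therefore demonstrates the pipeline's geometric and statistical
correctness — detection arithmetic, curve filtering, coordinate plumbing,
morphometric formulas, agreement statistics — not clinical-grade
performance on patient radiographs, which requires trained backends and
clinical data outside this package's scope.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use phantom studies sized for a
desk run: 5–14 vertebrae per image for unit tests, a 40-vertebra column for
the folded-normal landmark-error check, 8 × 14 vertebrae with 2 px landmark
noise for the end-to-end agreement study, 10⁴ simulated pairs for LOA
coverage, and 200 seeded trials for the RANSAC-versus-enumeration
comparison. Every stochastic component (phantom noise, oracle landmark
noise, RANSAC sampling) takes an explicit integer seed, and identical
spec + seed reproduces outputs bit-identically.

## Known limitations

* The reference segmentation backend assumes bright-on-dark bodies with
  clear gaps; fused or overlapping bodies merge into one component (their
  shared centroid usually survives the curve filter, but morphometry is then
  wrong for both). Learned backends should replace it on real data.
* Vertebral level labels are assigned by position (cranial → caudal) or
  nearest-reference lookup, never from image content.
* Collapse percent is within-vertebra; crush without an adjacent-level
  reference reads as 0 %.
* Greedy matching is assignment-optimal only for separated, spine-like
  reference geometries; on adversarial point clouds it is a lower bound on
  the optimal TP count.
* DICOM input is not parsed; convert to 16-bit PNG/TIFF upstream.
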