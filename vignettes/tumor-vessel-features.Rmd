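---
title: "Quantifying tumor-vessel involvement: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-vessel involvement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`pancvas` turns co-registered 3D segmentation masks of a pancreatic tumor
and the five major peripancreatic vessels (CA, CHA, SMA, PV, SMV) into a
quantitative description of vascular involvement: skeleton-based radius and
tumor-distance profiles, an encasement angle, contact measures, tumor shape
features, published logistic risk scores, and per-vessel involvement
models. This vignette explains the methods behind each step, the tunable
parameters and their defaults, the numerical choices, what the synthetic
phantoms do and do not emulate, and the package's known limitations.

# Input geometry

All geometric computation runs on isotropic grids. `resample_isotropic()`
resamples every mask with nearest-neighbour interpolation (labels are
categorical; linear interpolation would invent fractional labels) to cubic
voxels, by default 1 mm, so voxel-unit thresholds and millimetres coincide.
Masks are assumed co-registered; the package performs no registration.

# Vessel centerlines

## Thinning

`skeletonize_graph()` reduces a tubular mask to a one-voxel-wide curve by
sequential topology-preserving thinning: border voxels are visited in order
of increasing Euclidean distance to the background (then lexicographic
index, for determinism) and deleted when they are *simple points* — a voxel
is simple when its 26-neighbourhood contains exactly one foreground
26-component and its 18-neighbourhood contains exactly one background
6-component touching a face neighbour — and not curve endpoints (voxels
with at most one foreground neighbour). Distance ordering makes the
surviving curve medial; the simple-point test guarantees the skeleton has
the topology of the input mask (26-connectivity for foreground,
6-connectivity for background).

The exact medial curve of a capped tube stops about one radius short of
each flat end, and a sequentially thinned tail can drift off-axis toward
the cap rim. Both artefacts are corrected for edges much longer than the
local radius (length ≥ 3 × the maximal inscribed radius, which excludes
blob-like structures): the strictly-decaying terminal run of the distance
profile is trimmed, and the curve is then extended from the trimmed tip
along its local tangent until it leaves the mask. On digital cylinders of
radius 3–6 this yields centerlines spanning the full tube length with every
surface voxel mapped to a skeleton voxel within (radius + 1).

## Graph decomposition and pruning

Skeleton voxels of degree 1 are endpoints; voxels of degree ≥ 3 are
junction voxels, and 26-adjacent junction voxels are merged into a single
junction (a thick junction region otherwise splinters into spurious
one-voxel edges). Terminal edges shorter than `max(prune_min, 0.5 × local
radius)` (default `prune_min = 5` voxels) are pruned as surface-noise
spurs. Each edge's voxel path is ordered from the end with the lower
lexicographic index so the profile sequences are reproducible.

## Branches

`split_branches()` assigns every vessel voxel to the edge owning its
nearest skeleton voxel (ties toward the lowest lexicographic index), so the
branch masks always partition the vessel mask. A manual branch-label volume
overrides the automatic assignment, mirroring workflows where branches are
delineated by an annotator. When one per-vessel feature record is needed
and a vessel has several branches, the tumor-nearest branch (smallest
minimum tumor distance; ties toward the longer branch) is used — the
involvement question concerns the segment at risk.

# Anatomical features

* **Radius profile.** The radius at a centerline voxel is the Euclidean
  distance transform of the vessel mask evaluated there — the
  inscribed-sphere radius. No cross-sections are fitted; this is exact for
  digital cylinders up to the half-voxel digitization ripple.
* **Encasement angle.** For every 2D slice of the vessel perpendicular to
  each grid axis, the fraction of in-slice (4-neighbourhood) boundary
  pixels within `contact_tau` voxels (3D Euclidean distance) of the tumor
  is computed; the feature is the maximum fraction over all slices and
  axes, rendered both as a fraction and in degrees (×360). The default
  `contact_tau = 3` voxels is the published contact threshold. Slices with
  fewer than `min_perimeter = 8` boundary pixels are skipped — at grid
  resolution a 3-pixel cross-section makes the ratio unstable. Degrees are
  the model input scale: per-degree odds ratios near 1.01–1.02 are the
  plausible published magnitudes.
* **Radius-distance products.** `D_n = R_n × dist_n` couples narrowing and
  proximity: involvement risk grows when either the radius or the tumor
  distance drops. `D_ratio` divides the mean product outside the
  tumor-proximal region by the mean inside it; tumor-adjacent narrowing
  depresses the inside mean and raises the ratio. The proximal region is
  the set of path voxels with tumor distance ≤ `roi_rho` (default 10
  voxels — about two vessel radii, wide enough to cover the contact zone of
  a tumor abutting a 3–6-voxel vessel, narrow enough to leave an outside
  group on typical fields of view; the value is configurable and recorded
  in output metadata). When either group is empty or the inside mean is
  zero the ratio is undefined and stays missing in the feature table; it is
  imputed as the neutral value 1.0 only at scoring time, with a warning, so
  models are total while raw features stay honest.
* **Contact area and length.** `C_area` counts vessel surface voxels within
  `contact_tau` of the tumor. `C_length` counts the distinct skeleton
  voxels that *contact* surface voxels map to under the
  nearest-skeleton-voxel map — i.e. the skeletal span of the contact
  region. Counting all mapped skeleton voxels regardless of contact would
  simply measure skeleton length, which contradicts the feature's purpose
  as a contact-length surrogate; the contact-restricted reading is used.

# Tumor morphology

* **Volume** is voxel count × voxel volume. **Surface area** is the area of
  the 0.5-isosurface extracted by marching tetrahedra after Gaussian
  smoothing with σ = 0.7 voxel. The smoothing is sub-voxel and exists to
  suppress the voxelization staircase: on a digital sphere of radius 10 the
  raw binary isosurface overestimates the analytic area by roughly 9%,
  while the smoothed mesh is accurate to about 1%. Marching tetrahedra is
  used because its case geometry can be derived on the fly (each cube
  splits into six tetrahedra; a tetrahedron's level crossing is a triangle
  or a quad), with no large case tables.
* **Sphericity** `π^(1/3)·(6V)^(2/3)/A` equals 1 for a perfect sphere;
  digital balls score within ±0.02 of 1, with residual deviations dominated
  by digitization noise rather than a systematic radius-dependent bias.
  **Compactness** is the printed surface-to-volume ratio `A/V` (1/mm),
  dimensional by construction.
* **Principal axes** are `4·√λ` of the covariance of physical voxel
  coordinates (the fitted-ellipsoid convention). **Flatness** is
  `major/medium ≥ 1` — deliberately the printed definition, although much
  of the radiomics literature uses a ≤ 1 convention (minor/major): the
  published tumor-score coefficient was fitted to the ≥ 1 scale, so scoring
  must use it. For blocky shapes `4·√λ` can slightly exceed the true
  extent (a uniform segment has 4σ ≈ 1.15 × its length), so the maximum 3D
  diameter — the exact largest pairwise distance between surface voxels —
  is guaranteed only to dominate 90% of the major axis.
* **First-order intensity statistics** (mean through entropy/uniformity
  over `n_bins = 32` histogram bins) stand in for the high-throughput
  texture catalog; the feature-table schema reserves namespaced columns so
  external texture extractors can be merged.

# Risk scores and models

The two published logistic scores ship as versioned JSON model files.
`RStumor = logistic(1.526 + 7.093·T_flat − 9.826·T_sphere)` takes raw
inputs: its coefficients are plausible on the natural scales of flatness
(≈1–1.6) and sphericity (≈0.4–1). `RSdeform` (intercept −1.098;
coefficients 0.663, −1.086, −0.745, 2.395 on `R_std`, `D_max`, `D_std`,
`D_ratio`) is evaluated on standardized inputs: raw radius-distance
products are in squared voxels with values in the tens to hundreds, on
which coefficients near ±1 would saturate the logistic — the published
scale only makes sense for z-scored features. The cohort standardization
used originally is not published, so the built-in model stores an identity
reference (mean 0, sd 1) and callers supply features standardized against
their own cohort; the reference is editable in the model JSON.

Per-vessel involvement models combine the encasement angle (degrees),
`RStumor`, and — for the veins PV and SMV only — `RSdeform`; arteries are
stiffer and deform less, and the deformation score carries signal only for
veins. `RStumor` is always retained regardless of its Wald p-value.
Feature selection, where used, ranks by Fisher score
`(μ₁−μ₀)²/(σ₁²+σ₀²)` (population variances) and filters by univariable
Wald tests at α = 0.05.

Fits are maximum-likelihood logistic regressions (IRLS via `stats::glm`,
convergence tolerance 1e−12, at most 100 iterations). Coefficients with
|β| > 15 trigger a non-fatal complete-separation warning — on standardized
or probability-scaled inputs, honest finite effects of that size do not
occur.

# Evaluation statistics

* **AUC** is the Mann–Whitney pair statistic with ties counted ½
  (computed via midranks), with a DeLong variance for the confidence
  interval (using the 0.975 normal quantile). The paired DeLong test uses
  placement-value covariances; two identical score vectors give z = 0,
  p = 1 by convention.
* **Operating cutoff** defaults to the Youden-optimal threshold
  (`score ≥ cutoff` is positive); ties are broken toward the *lower*
  cutoff, favouring sensitivity — the appropriate asymmetry when the cost
  of underestimating involvement is surgery in an unresectable patient.
* **Proportions** (sensitivity, specificity, PPV, NPV) carry exact
  Clopper–Pearson 95% intervals, appropriate for the small per-vessel
  event counts typical of surgical cohorts.
* **McNemar** uses the exact binomial test when discordant pairs b + c
  < 25 and the continuity-corrected χ² otherwise.
* **Hosmer–Lemeshow** uses equal-count risk groups (default 10) with
  df = groups − 2, the reference appropriate for fitted models.
* **Decision curves** report `NB(t) = TP/n − (FP/n)·t/(1−t)` against
  treat-all and treat-none policies.
* **Nomograms** map each feature's range onto 0–100 points (the feature
  with the largest |β × range| spans exactly 100), with the reference value
  at the range endpoint minimizing the linear predictor; total points
  invert exactly to the model probability.

# Synthetic phantoms

The phantom module exists so every geometric claim is testable without
patient data. It emulates: tubular vessels (straight, curved, Y-shaped)
with known centerlines and radii, flat-capped and rasterized as unions of
thin tangent disks; optional smooth (Gaussian-profile) stenosis near the
tumor; ellipsoidal tumors; wrap tumors — shell sectors of known angular
width around a vessel, the ground truth for the encasement angle; and
tabular feature/outcome data drawn from the logistic generative law of the
risk scores. Scenes are deterministic given a seed, per-structure
substreams keep draws independent (adding a vessel never perturbs the
tumor), and every truth record re-renders its masks exactly.

Two wrap-phantom dimensions are set by explicit geometric analysis rather
than convention. First, a contact threshold of τ = 3 voxels adds roughly
`2·√(τ²−g²)/r` radians of spurious arc at radial gap g; the default wrap
vessel radius of 24 voxels keeps this near +13°, inside the ±18°
(0.05-fraction) recovery band used in validation. Second, because the
encasement maximum runs over all three axis-aligned slice stacks,
near-tangent *longitudinal* slices of a long wrap are in contact over the
whole wrap span and can exceed the true sector fraction; the default wrap
span (10 voxels on a length-50 vessel) keeps longitudinal fractions well
below the cross-sectional truth. These are phantom design choices that let
a discrete estimator be validated against continuous ground truth; the
estimator's parameters themselves are untouched.

What the phantoms do **not** emulate: CT intensity and noise (masks are
clean binary), anatomically realistic peripancreatic geometry (vessels are
parallel tubes), segmentation error, registration error, or partial-volume
effects. Passing phantom tests therefore validates the geometry and
statistics of the implementation — not robustness to segmentation quality,
which on real data dominates.

Scale invariance holds in the resolution-refinement sense: digitizing the
same physical scene twice as finely (and expressing the physical contact
threshold in the finer voxels) leaves the encasement fraction within 0.05
and doubles the recovered radii. Holding the threshold at 3 voxels while
scaling the scene changes the physical question — the contact band then
subtends a smaller angle — and is not an invariance one should expect.

# Numerical choices and degenerate inputs

* Distance transforms are exact squared-distance lower-envelope transforms
  (separable, per-axis), not chamfer approximations.
* Population (divisor-n) standard deviations are used in all feature
  statistics, matching the printed formulas.
* Empty tumor masks give zero encasement and contact; empty vessels,
  empty sequences, single-class outcomes, and coplanar tumors raise typed
  errors rather than returning numbers.
* Undefined `D_ratio` stays missing in tables (empty CSV cell, never 0)
  and is imputed as 1.0 only at scoring time.
* Simulation sizes in the validation suite (200,000 draws for coefficient
  recovery; 200 replicates for calibration; 500 for the null-calibration
  of Wald p-values; 96³ default phantom grids) are chosen so the full
  suite runs in well under an hour on a single core while leaving Monte
  Carlo error far inside the asserted tolerances.

# Known limitations

* Features are computed on binary masks; no sub-voxel centerline or
  surface refinement is attempted beyond the smoothed isosurface.
* The skeleton radius is the inscribed-sphere radius, which under-reads in
  non-circular cross-sections (e.g. a compressed vein reads its minor
  radius — arguably the clinically relevant one for stenosis).
* The published per-vessel models cannot be reconstituted exactly (the
  original study reports odds ratios without intercepts or the
  standardization of the deformation score), so the package reproduces the
  model *architecture* and refits coefficients on the user's data.
* Vessel-wall versus lumen distinction, perivascular fat analysis, 2D
  single-slice variants, and the full high-throughput texture catalog are
  out of scope.
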