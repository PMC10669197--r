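---
title: "Vessel morphometry and age prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel morphometry and age prediction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`vesselmorph` quantifies the geometry of large intracranial arteries —
typically the left and right internal carotid arteries (ICA) and the basilar
artery (BA) — in 3D time-of-flight MR angiography, and regresses subject age
on the resulting features. The pipeline is:

1. **Segmentation.** Seeded region growing on the intensity volume: the mask
   is the set of voxels at or above a global threshold (absolute, or a
   percentile of the volume) that are connected to a seed.
2. **Centerline.** Topological thinning of the mask to a one-voxel-wide
   skeleton; Dijkstra's algorithm between two annotated endpoints on the
   mm-weighted 26-adjacency graph; cubic smoothing splines per coordinate
   against chordal arc length; uniform arc-length resampling.
3. **Morphometry.** Six tortuosity descriptors — curve length $l_c$,
   Euclidean length $l$, relative length $RL = l/l_c$, sum of angle metrics
   $SOAM = \sum_i (180^\circ - \varphi_i) / l_c$, product of angle distance
   $PAD = SOAM / RL$, triangular index
   $TI = \frac{1}{n}\sum_i (a_i + b_i)/c_i$ — plus seven diameter statistics
   (mean, min, max, SD, 25th/50th/75th percentiles) of twice the Euclidean
   distance transform sampled along the centerline.
4. **Cohort assembly.** 3 segments x 13 features = 39 features per subject,
   with explicit exclusion criteria replacing visual QC.
5. **Modeling.** Six regression families (random forest, linear, AdaBoost,
   gradient boosting, Bayesian ridge, regularized gradient-boosted trees)
   under four-fold cross-validation, scored by Pearson r, RMSE, MAPE and
   $R^2$, with impurity-based feature importances for the tree families.

A synthetic phantom module provides parametric curves with closed-form
geometry, volumetric tube phantoms, and tabular cohorts with known
generating coefficients, so every stage is testable without clinical data.

# Conventions and key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| voxel indexing | 0-based | — | matches the annotation files produced by common Python tooling; mm position is `origin + index * spacing` |
| growing/skeleton connectivity | 26 | — | diagonal continuity of thin 3D skeletons |
| inclusion rule | percentile 99 (pipeline), absolute midpoint for phantoms | intensity | simplest reproducible rule; the source workflow's criterion is unstated, so it is configuration |
| resampling step | 0.5 | mm | sub-voxel for typical TOF spacing; all angle descriptors are computed on this uniform sampling |
| spline degrees of freedom | `0.5 * n` points | — | enough freedom to follow anatomy while suppressing voxel jaggedness; bounded below by 4 |
| QC chord/path ceiling | 1.0 (disabled) | — | a straight vessel is legitimate; tighten (e.g. 0.8) for ICAs to catch shortcut paths |
| QC snap bound | 5 | mm | an annotation farther than this from the skeleton indicates a failed segmentation or label |
| diameter sampling | value at containing voxel | mm | matches computation on a binary mask; trilinear interpolation available via `interpolate = TRUE` |
| percentiles / SD | linear interpolation / population | — | stated so results are reproducible bit-for-bit |
| angles | degrees | deg, deg/mm | matches the descriptor family's published formulation |

## Ambiguity in PAD

The flat rendering of the product-of-angle-distance descriptor admits both a
product and a quotient reading. The package defaults to the quotient
`SOAM / RL`, which reduces to SOAM for straight segments and penalizes
winding twice; `pad_definition = "soam_times_rl"` selects the product. The
choice is surfaced as an argument rather than silently resolved.

## Anchored thinning

Plain homotopic thinning of a capped tube erodes roughly one radius from
each end before the axis emerges, which would bias curve lengths short by
several millimetres. `skeletonize(mask, anchors = endpoints)` protects the
annotated endpoint voxels from deletion (constrained thinning), so the
skeleton spans the full annotated extent. The pipeline passes the
annotations as anchors automatically; without anchors the behavior is the
classic one.

## Dijkstra shortcuts

On a highly tortuous vessel the skeleton can contain spurious bridges, and
the shortest path will prefer them: the path is then *shorter* than the
correct centerline. This failure mode is intentional (it is what the
algorithm optimizes) and is the reason the QC stage exists: a chord/path
ratio higher than anatomically plausible flags the segment.

# The phantom world

The generator emulates exactly what the downstream stages consume:

- **Curves:** straight lines, helices, planar sinusoids and C1 arc-chain
  "siphons" (the C-shape of the carotid siphon), all with closed-form or
  quadrature ground truth. An independent dense-polyline oracle re-derives
  all six tortuosity descriptors with separate code, so oracle agreement is
  a real cross-check, not a tautology.
- **Volumes:** tubes rasterized on anisotropic grids (default 0.5 mm
  isotropic, 128^3 available; the demo uses 64 x 64 x 48 for speed), bright
  vessel on darker background, additive Gaussian noise clipped at zero.
  This exercises threshold-based growing; it is *not* an MR physics model —
  no flow effects, coil inhomogeneity, or partial-volume modeling — so a
  green segmentation test establishes correctness of the algorithm, not
  robustness to clinical artifacts.
- **Volumetric subjects:** three non-overlapping tubes (two helical
  ICA-like, one near-straight BA-like) whose radii increase linearly with
  an assigned age (0.008 mm/year around a reference age of 49.3), giving a
  cohort whose mean diameter is monotone in age by construction.
- **Tabular cohorts:** 39 features drawn independently from truncated
  normals on the scale of adult intracranial arteries, and
  `age = intercept + beta * features + N(0, noise_sd)`. The default world
  targets a cohort of mean age 49.3 and SD about 16.5 years, with the
  signal carried mainly by the mean-diameter features (the strongest
  coefficient on the right ICA, matching the importance structure the
  pipeline is designed to detect). These distributions are declared
  fixtures, not estimates of any real cohort; independence across features
  in particular is a simplification that real morphometry violates.

Generator defaults are part of the stated world of the test suite and are
not tuned against test outcomes.

# Modeling choices

- **Reference hyperparameters.** Each family carries a registry of allowed
  hyperparameter names seeded with the published reference configuration
  (e.g. random forest: 74 trees, depth 14, `max_features = "sqrt"`). When
  randomized search is disabled (the default), these values are used
  verbatim, which makes runs reproducible.
- **Native trees.** No CART/forest/boosting package is available in the
  supported dependency set, so the package implements CART regression trees
  in C++ (variance-reduction splitting, per-node feature subsampling,
  impurity-gain importances) and assembles random forest (bootstrap +
  mtry), AdaBoost.R2 (weighted bootstrap, loss-scaled stage confidence,
  weighted-median aggregation), LAD gradient boosting (sign-gradient trees
  with median leaf updates) and a second-order regularized boosting mode
  (leaf value $\sum g/(n+\lambda)$, gain with $\lambda$ and $\gamma$,
  row/column subsampling) on top. `criterion` strings naming other split
  impurities are accepted for registry compatibility but the splitter is
  always variance-based; exhaustive absolute-error splitting is
  quadratic per node and changes results marginally at these sample sizes.
- **Bayesian ridge** is the standard evidence-maximization algorithm
  (Gaussian weight prior, gamma hyperpriors on both precisions) on centered
  data, iterated to a coefficient-change tolerance.
- **MAPE** uses absolute errors: a signed version could be negative,
  contradicting the metric's name and its reported use.
- **$R^2$** is computed directly on each validation fold and can be
  negative there; aggregation is mean ± SD over the four folds.
- **Inner protocol.** Randomized search, when enabled, scores sampled
  configurations by mean absolute error over a 3-fold split of the training
  portion only; the outer validation fold never participates. Whether
  hyperparameters should be re-tuned per outer fold is genuinely open; the
  package supports both, with fixed-reference-values as default.
- **Importance.** Split-quality reductions are accumulated per feature over
  all trees, normalized to sum to one, and averaged across folds; ranking
  ties break by feature-column order.

# Numerical notes

- Interior angles use `atan2(|u x w|, u . w)`, which is stable near 0 and
  180 degrees where `acos` loses precision; this is what makes the
  rigid-motion invariance of the descriptors hold to 1e-9 relative.
- The turning sum of a polyline inscribed in a smooth curve under-counts the
  total curvature by one angular step, so SOAM converges at O(1/n) in the
  sampling density; TI converges to 1 on smooth curves for the same reason.
  Descriptors are therefore always compared at matched or dense samplings.
- The distance transform is the exact anisotropic Euclidean transform
  (separable lower-envelope algorithm), with distances to in-volume
  background voxels only.
- Degenerate inputs fail loudly with located errors: closed loops (RL),
  repeated points (SOAM), fold-backs (TI), points outside the mask
  (diameters), seeds failing the inclusion rule, disconnected endpoints
  (distinct "no path" error class).

# Known limitations

- Single-tube topology per segment: no bifurcation handling or anatomical
  labeling beyond the user's annotations.
- Thinning is a curve-skeleton algorithm; on masks much wider than long it
  can produce medial-surface fragments before converging.
- The NIfTI reader supports the single-file little-endian subset the
  pipeline writes (datatypes uint8/int16/int32/float32/float64, spacing
  from `pixdim`, origin from the sform translation); it ignores rotation
  matrices.
- The phantom cohort cannot certify clinical performance: it establishes
  that the pipeline recovers known geometry and known statistical structure
  at stated tolerances, nothing more.
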