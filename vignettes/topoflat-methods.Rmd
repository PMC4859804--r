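---
title: "Quantifying projection topography with average flatmaps"
author: "topoflat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying projection topography with average flatmaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoflat)
```

## The problem

Anterograde tract tracing maps where the axons of a cortical source region
terminate in a target region. Comparing such projections across animals of
different postnatal ages is hard for two reasons: brains grow, so absolute
positions and extents are not comparable; and both the source and target are
curved sheets cut into sections, so "where" must be expressed in a
surface-intrinsic coordinate system rather than in section or atlas
coordinates. `topoflat` implements a quantification chain for exactly this
situation, developed for projections from the retrosplenial cortex (RSC,
areas A29 and A30) to the parahippocampal region (PHR: presubiculum PrS,
parasubiculum PaS, and medial/lateral entorhinal cortex MEC/LEC) in
postnatal rats, and tests whether those projections are topographically
organized from the earliest ages.

The chain has four stages, each a module of the package:

1. **Injection normalization** (`flatten_injections()` and friends): each
   3D injection coordinate is transposed to the closest point on a
   triangulated model of the source area's pial surface, and expressed as
   normalized coordinates `rc = d_r / (d_r + d_c)` (cumulative midline arc
   distances to the rostral and caudal ends; 0 = rostral) and
   `dv = d_v / (d_v + d_d)` (Euclidean distances to the ventral and dorsal
   border polylines; 0 = ventral).
2. **Average flatmap** (`average_flatmap()`): per-animal, per-section
   transverse extents of each target subdivision are divided by that
   animal's own maximum for the subdivision, resampled onto `smax`
   dorsoventral rows, averaged across animals, divided by the mean
   normalized dorsoventral extent, and converted row-by-row into integer
   counts of square bins (`round(T_i * smax)`, half-up). Because every
   animal is normalized to itself before averaging, the construction is
   invariant to global brain size — the property that makes pooling across
   ages valid.
3. **Label mapping** (`map_observations()`, `pool_maps()`,
   `center_of_mass()`): dense-plexus boundary intervals (graded 1–3 by
   density, the densest plexus of each experiment defining grade 3) and
   single-fiber positions are normalized by each section's measured extent,
   flipped onto a common proximal/medial → distal/lateral axis where the
   measurement reference border demands it (PaS is measured from its distal
   border), and binned. Each experiment's map is normalized to its densest
   bin so plexus grades and fiber counts become comparable; pooled maps
   re-normalize, with optional subgroup weighting so every subgroup has
   equal impact. The quantitative readout is the center of mass of labeling
   per assembled field (PrS layers I/III; deep PrS+PaS; deep MEC+LEC) on
   0–1 axes (dorsoventral: 0 = ventral; transverse: 0 = proximal/medial).
4. **Statistics** (`fit_topography()`, `cluster_experiments()`): each CoM
   coordinate is regressed on `rc`, `dv` and age (days), starting from the
   model with all two-way interactions and removing, one per refit, the
   interaction with the smallest absolute standardized beta among those not
   significant at `alpha` (two-sided t-test), until only main effects and
   significant interactions remain. For cluster analysis, flatmaps are
   smoothed with a 5×5-bin Gaussian (σ = 1.5 bins), pairwise-correlated,
   and k-means is run on the correlation matrix over a range of k with the
   within/between variance ratio (SSW/SSB) reported per k.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `span` | 0.5 | fraction of points | loess span for border smoothing; the borders are manually delineated polylines, and a moderate span removes delineation jitter without flattening real curvature |
| `smax` | `"auto"` | rows | flatmap row count; `"auto"` uses the maximum per-animal section count, so the best-sampled animal sets the resolution |
| `alpha` | 0.05 | — | significance criterion for keeping an interaction |
| `age_max` | 19 | days | oldest animals entering the regressions; the study design has no samples between P19 and P27, so the regression sample stops at P19 |
| `size`, `sigma` | 5, 1.5 | bins | Gaussian smoothing kernel before clustering |
| `threshold` | 0.1 | ratio units | minimum drop in SSW/SSB regarded a substantial improvement when choosing k |

## Numerical choices

* **Border smoothing** is tricube-weighted local linear regression
  (`stats::loess`, degree 1) of each coordinate against cumulative arc
  length. A degree-1 local fit reproduces straight borders exactly, so
  noiseless input passes through unchanged.
* **Point-to-surface transposition** minimizes Euclidean distance over all
  triangles (closest-point-on-triangle, vectorized); ties between triangles
  resolve to the lowest index, making results deterministic.
* **Border distances** (`d_d`, `d_v`) are Euclidean point-to-polyline
  distances, not geodesics along the surface: the transposition is defined
  by a shortest straight vector, and on strips with the curvature of caudal
  cortex the difference is well below the bin resolution.
* **Midline** = pointwise midpoints of the two borders after resampling to
  equal arc-length fractions.
* **Row resampling** of a variable number of sections onto `smax` rows uses
  linear interpolation of normalized extent against normalized dorsoventral
  position at row centers, clamped to the outermost section values: each
  animal's sections tile its own extent, so every row receives a value and a
  constant profile stays constant at any `smax`.
* **Bin membership** is half-open: interval bins by bin-center in
  `[start, end)`, fiber bins by position in `[left, right)` with the last
  bin closed, so bin counts conserve fiber mass exactly.
* **Rounding** of `T_i * smax` is half-up (ties away from zero), matching
  "rounded to the nearest integer" in spreadsheet convention rather than
  IEEE round-half-even.
* **Ragged-grid matching**: rows with different bin counts are compared and
  interpolated via normalized transverse position — the grid is ragged by
  construction and bins "at the same location" are defined by their relative
  position along the row.
* **Masked Gaussian smoothing** renormalizes the kernel over the bins that
  exist at each target (normalized convolution). This preserves constant
  maps and lets no zero-padding bleed in from outside the region; it does
  not conserve total mass at boundaries, a deliberate trade-off since the
  smoothed maps feed correlations, not densitometry.
* **Elbow rule**: the cluster count is fixed where adding a cluster drops
  SSW/SSB by less than `threshold` in absolute terms. A relative-improvement
  rule degenerates once the ratio is near zero (splitting a perfectly
  separated cluster still "improves" it by a large fraction of almost
  nothing), so the absolute form is the default; the published choice this
  emulates was explicitly a judgement call, and the threshold is exposed.
* **Interaction terms** are products of the raw (uncentered) 0–1 coordinates
  and age in days. This matches how the original models were specified and
  means main effects are conditional effects at zero; VIFs for models that
  retain an interaction are accordingly large, which is a property of the
  parameterization, not a data problem.
* **Elimination convention**: an interaction is removed when its p-value is
  at or above `alpha`. Hence `alpha = 0` strips every interaction (the
  main-effects model) and `alpha = 1` keeps the full model; the defaults
  reproduce the published procedure at `alpha = 0.05`.
* **Degenerate inputs** fail loudly: all-zero subdivisions are excluded with
  a warning, zero-variance flatmaps abort correlation with the offending
  experiment ids, empty experiments carry an `empty` flag and yield `NA`
  centers of mass that the regressions exclude (and count in the log).

## The synthetic-data generator

`gen_study()` exists so the entire chain can be exercised and validated
without histological material. It emulates:

* **Animals** (`gen_animals()`): smooth unimodal transverse-extent profiles
  per subdivision, scaled by a monotone growth factor `1 + 0.05 * age` and
  a base dorsoventral extent of 4.5 mm at a 300 µm series spacing, so a
  P19 animal has 29 sections and section counts grow with age; measurement
  noise is multiplicative lognormal (sdlog 0.08, roughly the reproducibility
  of manual extent measurements).
* **Surface and injections** (`gen_surface()`): a strip 8 mm long and 3 mm
  wide, cylindrically bent at 0.15/mm by default, with injections displaced
  0.4 mm off-surface at known (rc, dv) ground truth.
* **Labeling** (`gen_projection()`): terminal fields centered at
  `mu_dv = 0.75 - 0.4 * rc` and `mu_tr = 0.3 + 0.4 * dv` (caudal injections
  label ventral target levels; dorsal injections label distal/lateral
  positions), with Gaussian spread 0.08 and per-experiment center jitter
  0.05 in flatmap units. Expected fiber counts follow
  `3 * exp(0.25 * (age - 1))`, so P1–P2 animals carry single fibers (about
  1–5) and density rises monotonically; from P12 the generator emits graded
  plexus intervals instead of fiber lists, with grade 3 at the modal rows
  and the interval taken from the 10%-of-peak level set of the generating
  Gaussian — mirroring the developmental shift from single unbranched
  fibers to an adult-like plexus. All of these numbers are generator
  choices, not measurements.

What the generator does **not** emulate: real cytoarchitectonic border
uncertainty, per-section registration error, tracer spill-over across the
A29/A30 boundary, asymmetric or multi-focal terminal fields, and subjective
variation in density grading. Passing recovery tests therefore shows the
pipeline is correct and unbiased under its own model assumptions, not that
those assumptions hold in tissue.

## Validation strategy and problem sizes

The test suite checks each stage against independent oracles: planar and
trapezoid geometry in closed form, dense-sampling distance oracles for the
surface projection, a hand-computed two-animal flatmap fixture, bin-center
enumeration for interval mapping, a normal-equations solve for the
regression coefficients and confidence intervals, and `car::vif` as a
cross-check of the auxiliary-regression VIFs. Property-style tests cover
scale invariance, mass conservation, normalization idempotence, subgroup
replication invariance, rigid-motion invariance and seeded determinism.
End-to-end recovery runs 100 seeded studies of 100 experiments each at the
generator's default noise and asks that the fitted `rc` slope on the
dorsoventral CoM and `dv` slope on the transverse CoM recover the
generating gradients in sign (≥95% of replicates) and magnitude (within
±30% in ≥90%). These problem sizes mirror the scale of the motivating
dataset (105 tracing experiments, 29-row flatmaps) while keeping the whole
suite around a minute.

## Interfaces

The package's surface is its functions: `run_pipeline()` orchestrates the
stages over in-memory tables or a study directory written by
`write_study()`/`read_study()`, and `scripts/acceptance.R` is a runnable
record of the headline computation. Tables are UTF-8 TSVs with one header
row; flatmap specifications and label-map sidecars are JSON. Axis
conventions are fixed everywhere: rc 0 = rostral, dv 0 = ventral,
transverse 0 = proximal/medial.

## Known limitations

* Area assignment of an injection (A29 vs A30) uses the nearest strip of a
  two-strip surface model, a geometric stand-in for cytoarchitectonic
  assignment; injections close to the boundary inherit its uncertainty.
* `d_d`/`d_v` are chordal distances; on very strongly curved strips the
  dorsoventral coordinate is mildly compressed near the borders (the
  curved-strip recovery test bounds the rc error at 0.02; dv distortion at
  the default curvature is below one bin).
* The elimination procedure inherits the usual caveats of stepwise
  selection: p-values of retained terms are conditional on the path.
* Missing-section interpolation assumes smooth variation between adjacent
  sections; a genuinely patchy projection would be over-smoothed.
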