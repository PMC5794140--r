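---
title: "Mapping social-ecological patches and livelihood benefits: methods"
author: "sepatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping social-ecological patches and livelihood benefits: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepatch)
```

## The problem

In semi-arid smallholder landscapes such as the Sudano-Sahelian zone,
rural livelihoods depend directly on provisioning ecosystem services:
crops, fodder, wild foods, medicine, wood and products that can be sold
or kept as living savings. Village-scale participatory assessments can
describe this dependence in detail, but land-use decisions are taken at
provincial scale. `sepatch` implements a pipeline for extrapolating a
village-scale assessment across a whole study area from open satellite
imagery:

1. classify two seasons of multispectral imagery into
   **social-ecological patches** — landscape units that match the
   vocabulary local people use (field, shrubland, depression, homestead,
   forest, bare soil), plus the water and urban land covers — with a
   hybrid decision-tree classifier;
2. convert the patch map into five **livelihood benefit** rasters
   (annual crops for consumption; nutritional diversity and medicinal
   uses; material assets and energy; saving/insurance; income) using a
   per-patch score table and two multiplicative weighting mechanisms;
3. assess map quality with a buffered **relative accuracy**, a standard
   confusion matrix, and landcover composition summaries.

A synthetic-landscape generator with known ground truth makes every
stage testable end to end without any external downloads.

## Patch classes

Eight categories with fixed integer codes (1 = bare_soil, 2 =
depression, 3 = field, 4 = forest, 5 = homestead, 6 = shrubland, 7 =
water, 8 = urban; 0/`NA` = nodata). Water and urban land are land
covers, not social-ecological patches: they are mapped, counted in the
landcover composition, but carry no benefit scores. Fallow is
deliberately absent as a category: its land cover ranges from bare soil
through shrubland-like regrowth, so no spectral rule can separate it,
and its services are representable as a combination of the classes that
are mapped.

## The hybrid classifier

### Data layers

The classifier operates on named raster layers from two seasons (dry
and rainy): the red, near-infrared and mid-infrared bands; per-season
NDVI, `(NIR − red)/(NIR + red)`; per-season tasseled cap brightness,
greenness and wetness; and the elevation model as layer `dem`. The
tasseled cap transformation is a fixed linear compression of the bands;
the shipped coefficient table is the published Landsat 8 at-satellite
reflectance set, restricted to the three modeled bands (red, NIR,
MIR = SWIR2). Any coefficient matrix with one column per available band
can be substituted, and the full six-band table is available via
`tct_coefficients_l8(full = TRUE)`.

### Preparatory steps: overlays

Classes that spectra alone cannot separate reliably — homesteads,
depressions, urban land — enter as vector overlays burned into the map
before the tree runs: every pixel whose center falls inside an overlay
polygon gets that overlay's class, later overlays override earlier
ones, and tree evaluation never overwrites an overlay pixel. Overlays
come either from digitized files (the authoritative path) or from
`detect_built_patches()`, a simplified object-based detector that
thresholds a brightness layer (strictly above the cut), extracts
8-connected components, and applies a size rule: components within the
size window become homestead candidates; larger components become urban
candidates only where they overlap a village point's neighborhood.

### The decision tree

The tree is binary: each node compares one layer against a threshold;
`>=` holds on the true branch, so ties route to the true branch
(stated once here, tested). Every leaf is a class. Rather than
hard-coding node criteria, the tree is derived from calibration data by
sequential class peeling (`derive_tree()`):

* Separability between two classes on a layer is measured by the M
  statistic, `M = |μ₁ − μ₂| / (σ₁ + σ₂)`, computed from the per-class
  sample mean and sample (n−1) standard deviation of calibration-point
  values. Calibration sets are small, hence the n−1 denominator.
* For each class in the peeling order, the candidate layers are those
  on which the class mean is *extremal* relative to all remaining
  classes. This is a deliberate sharpening of "the layer that best
  separates the class from the pool": one binary threshold can only
  peel off a class that sits at one end of the pool on that layer.
* Among candidates, the layer with the largest minimum pairwise M
  against the pool wins. If that M falls below `m_threshold` (default
  1.0, a conventional good-separability cut), derivation stops with a
  calibration error naming the hardest class pair — no silent guessing.
* The threshold is the midpoint between the class mean and the nearest
  remaining-class mean; the last remaining class is the default leaf,
  so k classes yield exactly k − 1 internal nodes.

The default peeling order — water, forest, depression (when no overlay
supplies it), shrubland, field, bare soil — peels the spectrally
extreme classes first and leaves the confusable low-biomass classes
(sparse shrubland vs field vs bare soil) for last, where
misassignments do the least structural damage. Trees serialize to a
small hand-editable YAML schema (`write_tree()` / `read_tree()`).

Classes that the survey cannot calibrate (fewer than two calibration
points) cannot enter the tree; they are skipped with a warning and, in
the packaged recovery experiment, their groundtruth points are excluded
from assessment and counted. This mirrors how an uncalibratable
category has to be dropped from mapping in practice (it is exactly what
happened to fallow).

### Numerical conventions

* Pixel cells are half-open, `[origin + i·px, origin + (i+1)·px)`, so
  every coordinate maps to exactly one cell; point-to-pixel lookup is
  by containing cell (equivalently nearest pixel center).
* Nodata in any layer a tree path touches makes the output pixel
  nodata; classification is otherwise total and deterministic, and the
  vectorized evaluator is held equal to a per-pixel recursive reference
  implementation by test.
* Reflectance means live in [0, 1]; synthetic noise draws are clamped
  to that range.

## Benefit mapping

Each benefit raster is, per pixel,

```
value = score(class, benefit) × d × a
```

where `d` is the homestead-distance weight when (class, benefit) is
distance-weighted (else 1) and `a` the shrubland-area weight when
(class, benefit) is area-weighted (else 1); both can apply to the same
cell. Water, urban and zero-scoring classes contribute exactly 0
regardless of weights; nodata propagates. The composite heat map is the
exact per-pixel sum of the five benefit rasters.

**Score table.** The scores are a mandatory, swappable configuration.
The shipped default encodes the qualitative patch-benefit relations on
an integer 0–5 scale per unit area (fields dominate annual crops;
shrubland and forest supply wild foods, medicine and wood but no annual
crops; every patch feeds livestock, so saving/insurance is positive for
all six patches; water and urban score 0 throughout). These defaults
are documented package choices, *not* a claim about the original
study's numeric scores, which were never printed; users replicating
that study should substitute their own table via the config.

**Distance weights** (`homestead_distance_weights()`). For fields and
shrubland, every benefit except saving/insurance loses value with
distance from homesteads (transport effort); livestock-mediated
saving/insurance does not. The weight raster bins the exact Euclidean
distance to the nearest homestead pixel (computed via `EBImage`'s
distance transform, in projected meters — a metric CRS is enforced)
into five annular zones of width 500 m by default, with weights
interpolated linearly from 1.2 (closest zone, including distance 0) to
0.8 (outermost and beyond). Zone bins are left-closed: `[0, w)` is
zone 1. Five 500 m zones give a ~2.5 km reach, a plausible scale for
management rings around Sahelian settlements; the width, zone count and
end weights are all configurable. Weights apply around every homestead
pixel, not only village centers — the conservative reading when the
alternative is unstated.

**Area weights** (`shrubland_area_weights()`). The value of shrubland
benefits depends on how much shrubland a village has: too little
cannot sustain pasture and species diversity, while beyond an upper
limit extra shrubland adds little. Village territories are Thiessen
(Voronoi) polygons of the village points — computed exactly by clipping
the extent rectangle with perpendicular-bisector half-planes, so
territory areas sum to the extent area — and each territory's
shrubland fraction is binned by breakpoints {0.02, 0.10, 0.25, 0.40}
into five categories with hump-shaped weights {0.8, 1.0, 1.2, 1.1,
0.9}. Every pixel of a territory shares its village's weight. An empty
territory gets weight 1.0 with a warning. Breakpoints and weights are
config; the defaults encode the qualitative hump, not published values.

Benefit maps are not normalized; any min–max scaling for display must
never feed back into computation.

## Accuracy assessment

**Relative accuracy** (`relative_accuracy()`). A groundtruth point is
correct if the disk of radius `buffer_m` (default 15 m, half a pixel)
around it overlaps at least one pixel of its true class. "Overlaps" is
defined as positive-area intersection of the open disk with the open
pixel cell — equivalently, the distance from the point to the closed
cell is strictly less than the radius; touching at a corner or along an
edge does not count. The edge case matters: a point at the exact center
of a wrong 30 m pixel with the correct class adjacent is *incorrect* at
buffer 15. At `buffer_m = 0` the measure reduces exactly to plain
point-in-pixel accuracy, and it is non-decreasing in the radius, which
is why relative accuracy is always at least the pixel-to-pixel
accuracy. The buffer absorbs GPS jitter and co-registration offsets, so
the measure reads as "does the map capture the composition of the
landscape here", not "is this exact pixel right". The overall figure is
point-pooled; the mean of per-class accuracies is also reported since
either convention is defensible. Urban groundtruth is excluded from
accuracy (a land cover mapped from overlays, conventionally assessed
with "–"); water is included.

`confusion_matrix()` provides the standard point-in-pixel cross-tab
with producer's (recall) and user's (precision) accuracies, and
`landcover_composition()` the per-class percentage of mapped pixels,
summing to 100 over all classes including water and urban.

## The synthetic landscape generator

`generate_landscape()` builds study areas with known truth on a 30 m
metric grid:

* **Mosaic.** Homesteads are small blocks clustered around village
  points; urban land is one contiguous block around a designated town;
  depressions are scattered elongated blocks; water, forest, shrubland
  and field grow from random nuclei by seeded region growing under
  pixel quotas; the remainder is bare soil. Defaults target a
  field-dominated mosaic (50% field, 20% shrubland, 6% depression, 3%
  homestead, 2% water, 1% forest, 1% urban) matching the composition
  range the method was developed for. Realized fractions are held
  within a stated tolerance (default 0.05) by test.
* **Overlays.** Homestead/depression/urban shapes are axis-aligned
  rectangles with edges on pixel boundaries, so the overlay polygons
  rasterize *exactly* to the corresponding truth labels — deliberately
  avoiding any ambiguity from pixel centers sitting on polygon edges.
* **Spectra.** Each season-band value is drawn from the class Gaussian
  of a signature model. The default signatures sketch plausible
  semi-arid phenology (fields bare in the dry season and green in the
  rainy season; depressions wet and green after the rains; water dark
  everywhere; built surfaces bright with high MIR), with per-band noise
  sd 0.01. No radiometric calibration is claimed: the paper-level
  requirement is only that classes be separable on the layers the tree
  uses, and per-class spectral statistics were never published.
* **DEM.** A smooth random bump field (base 320 m, relief ±15 m) with
  depressions and water carved 8 m down, so depressions coincide with
  local minima and elevation-based tree nodes can be exercised.
* **Surveys.** `sample_transects()` emulates transect walks: straight
  walks from village points with random headings, stops every 100 m
  (inclusive endpoints: a 3 km walk has 31 stops), truth labels taken
  at the undisturbed stop location, then isotropic GPS jitter (default
  5 m, clamped to the extent). Walks leaving the extent are truncated
  with a warning. Points are split 50/50 into calibration and
  groundtruth roles, stratified by class — the original study did not
  state its split, so an even stratified split is the package default.
  27 transects of 3 km yield on the order of 800 points, matching the
  study scale.

All randomness flows through explicit `seed` arguments (via
`withr::with_seed`); no global random state is touched, and identical
seeds give bit-identical rasters.

### What the generator does not emulate

Gaussian class spectra have no spatial autocorrelation of noise, no
mixed pixels at patch boundaries, no clouds or shadows, no atmospheric
or terrain-illumination effects, and no fallow-like categories with
overlapping signatures. Passing recovery tests therefore demonstrates
the *machinery* — that the pipeline recovers a landscape whose classes
are separable at the stated M levels — not that real Landsat scenes of
real provinces would classify at these accuracies; the original study's
50% shrubland and 25–33% forest accuracies show what heavily
overlapping signatures do in practice.

## Validation experiments and problem sizes

The packaged experiment (`recovery_experiment()`) runs the full chain
on a 300 × 300 grid (9 × 9 km at 30 m) with 27 transect walks —
chosen as the largest size at which the whole suite iterates
comfortably on one CPU — and reports relative accuracy at buffers 0,
15 and 30 m plus the smallest best-layer pairwise M among tree
classes. Under the default conditions (noise sd 0.01, 5 m GPS jitter)
pairwise M stays well above 1 and relative accuracy at 15 m exceeds
95%; with zero spectral and GPS noise, recovery is exact (100%),
because midpoint thresholds cannot misroute pixels that sit exactly on
their class means. Property suites run on smaller grids: oracle
equivalence (vectorized vs per-pixel classification, composition,
confusion, heat-map summation) on twenty random 16 × 16 instances,
weight contracts on one hundred random valid configurations, Voronoi
partition checks on fifty random village sets.

## I/O and formats

Rasters are exchanged as Esri ASCII grid — a standard plain-text
raster format — with CRS units in a `.prj` sidecar; integer rasters
round-trip bit-identically, floats at full double precision. Vectors
(points, overlay polygons) are GeoJSON. Patch maps ship with a
code↔label legend file, trees as YAML, reports as JSON and TSV, and
the whole pipeline is driven by one YAML config with exactly one of a
`synthetic` or `real` input block (`run_pipeline()`). Artifacts are
byte-identical across reruns of the same config and seed; the
provenance record carries the config hash, seed and package version.

## Known limitations

* The numeric score table, zone radii and shrubland breakpoints are
  documented defaults, not the original study's unpublished values;
  conclusions about benefit *levels* depend on supplying real scores.
* The object-based built-up detector is a simplified stand-in for
  manual interpretation; the overlay path is authoritative.
* Component polygonization returns outer rings only (holes are
  dropped), and diagonal-only pinch points are chained arbitrarily —
  adequate for compact built-up blocks.
* Cloud/shadow handling is nodata-in → nodata-out; no masking logic is
  provided.
* Only the red/NIR/MIR bands are modeled; full six-band scenes are
  accepted but not synthesized.
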