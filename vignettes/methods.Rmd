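---
title: "Monitoring selective logging and deforestation with loggrid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring selective logging and deforestation with loggrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loggrid)
```

## The problem

Selective logging removes individual commercial trees while leaving the
canopy largely intact. At Landsat resolution (30 m, ~0.1 ha pixels) its
footprint is subtle: logging decks (log staging areas) one or two pixels
wide, one-pixel logging roads, and scattered tree-fall gaps, all of which
close again within one to four years. Conventional forest-change mapping
either misses these features or — worse — maps them as small clearings,
conflating degradation with deforestation. `loggrid` implements an
integrated annual monitoring workflow that separates the two processes and
reports disturbance intensity on a spatially stable grid:

1. **Forest mask** (object-based): multiresolution region-merging
   segmentation of the base-year image, rule-based classification of
   segments into forest/non-forest, and an annual update that adds new
   clearings while deliberately keeping sub-hectare logging evidence inside
   the forest polygons.
2. **Disturbance evidence** (sub-pixel): linear spectral mixture analysis
   (LSMA) decomposes each pixel's spectrum into soil, vegetation and shade
   fractions; forest pixels with soil fraction at or above 10% are flagged
   as logging evidence.
3. **Grid accounting**: pixel counts per fixed 300 m cell yield a
   disturbance intensity (flagged pixels / forest pixels) classed as very
   low (1–5%), low (5–10%), medium (10–50%) or high (>50%), plus annual
   rates, land-cover change matrices and recurrence counts.

Stages 1–2 are preceded by relative radiometric normalization over
pseudo-invariant features (PIFs) so that one soil-fraction threshold is
meaningful across the whole series.

## Models and conventions

### Linear spectral mixture analysis

A pixel spectrum $y \in \mathbb{R}^B$ is modelled as $y = Ef + \varepsilon$
with $E$ the $B \times 3$ endmember matrix and $f$ the fraction vector.
The default solver enforces the full simplex constraints
($\sum_i f_i = 1$, $f_i \ge 0$): fraction semantics require them, and the
constrained problem is solved *exactly* by enumerating the faces of the
simplex — the active set of the optimum must appear as one of the seven
face problems, each of which is an equality-constrained least-squares
problem whose solution is affine in $y$ and therefore vectorises over all
pixels as a single matrix product. Unconstrained, sum-to-one-only and
clip-to-[0,1] modes are provided for sensitivity checks, since the original
formulation leaves the constraint regime unstated. The disturbance
threshold comparison is inclusive (soil $\ge$ 0.10).

### Radiometric normalization

The normalization technique is named in the source method but not its
selection rule; our rule is deterministic and testable: PIF candidates are
pixels valid in both scenes, outside an optional change mask, in the lowest
decile of summed absolute band differences after a coarse median-ratio gain
guess. Per band, `reference = gain * target + offset` is fitted by OLS
(optionally one 2.5-MAD trim pass), and the earliest scene anchors the
series by default. Both choices are configurable and logged in the run
manifest.

### Segmentation

The region merging minimises the standard colour/shape heterogeneity
increase (colour: size-weighted standard deviations; shape: compactness
$l/\sqrt{n}$ and smoothness $l/b$), stopping when the cheapest fusion
exceeds `scale^2`. Merging is globally lowest-cost-first with lowest-id tie
breaking, so segmentations are bit-reproducible. Conventional scale values
(10 for the base year, 50 for the annual update, with 0.8/0.2 and 0.9/0.1
colour/shape weights) assume 8-bit digital-number imagery, so reflectance
is multiplied by `value_scale` (default 255) before heterogeneity is
computed; this keeps the published parameter values meaningful on [0, 1]
data. Bit-identical equivalence with any commercial implementation is a
non-goal — the contract is determinism, the segmentation invariants, and
truth recovery on synthetic scenes.

The classification rules of the original decision tree are unpublished. We
ship a declarative, ordered rule list over segment attributes (defaults:
mean soil fraction $\ge$ 0.40 or mean shade fraction $\ge$ 0.70 is
non-forest, remainder forest). These defaults are placeholders to be tuned
per scene; every pipeline run logs the rule set used.

### Area criterion and minimum mapping unit

Two thresholds keep logging evidence inside the forest: non-forest islands
smaller than `min_area_ha` (default 1 ha) whose border majority-touches
forest are absorbed back into forest after base-year classification, and
candidate new clearings in the annual update must reach `mmu_ha` (default
1 ha ≈ 11 pixels). Neither value is stated in the source; 1 ha is far below
the 6.5 ha minimum of regional deforestation monitoring and comfortably
above the 1–2 pixel logging features the method must retain.

### Grid accounting

Cells are 300 m (10 × 10 pixels), anchored at the raster origin and fixed
across all years — spatial stability across time is the point of the grid.
Intensity uses forest pixels at that date as the denominator (disturbed
pixels count as forest; deforested ones do not). Intensity classes are
lower-inclusive/upper-exclusive except HIGH, which includes 0.50 exactly,
since a pixel-count ratio can hit 50/100. The deforestation rate for an
interval is new-deforestation area over previous forest area; the
disturbance rate is reported in a cell variant (forest area of cells newly
exceeding the 5% level) and a pixel variant (newly flagged pixels), since
"newly disturbed" has no published operational definition. Partial edge
cells are excluded from area summaries by default, and the Table-4-style
composition is emitted both as a forest-area allocation and a whole-cell
allocation (the source is ambiguous between the two).

### Accuracy assessment

Stratified random sampling (the canonical design: 75 undisturbed + 50 per
disturbance class and year, very low merged into low for interpretability)
produces a sample table meant to be labelled externally by an interpreter
and round-tripped as CSV. Error matrices allow reference-only classes as
extra columns; user's accuracy divides the diagonal by the full row total,
producer's by the column total, and overall accuracy excludes reference
units whose class has no map counterpart from the denominator — that
convention reproduces the published pooled matrix figure (583/889 = 65.6%)
exactly. Published off-diagonal cells of the pooled matrix are not fully
marginal-consistent; wherever the package's tests reconstruct that matrix,
the diagonal, reference column totals and High row are treated as
authoritative and the remaining cells are a consistent completion.

## The synthetic landscape generator

`simulate_landscape()` produces the ground truth that every downstream
stage is validated against. It emulates, per year: a ragged agricultural
frontier (19% non-forest initially), deforestation growing as contiguous
2–4 ha patches from that frontier (2% of remaining forest per year),
logging blocks covering ~25% of the forest per year containing decks on a
jittered lattice at 225 m spacing (the observed 200–250 m deck distance),
one-pixel roads linking the decks, scattered canopy gaps, and abrupt
canopy recovery after 2 years (within the observed 1–4-year closure
range). Fraction signatures put undisturbed forest soil at 0.03 (safely
below the 10% threshold) and every logging feature at or above 0.15.
Scenes are rendered by the forward mixing model plus i.i.d. Gaussian band
noise, clipped to [0, 1].

Randomness is streamed per (seed, year), so extending a series never
perturbs earlier years, and deck placement is a jittered lattice rather
than a point process so deck counts are exactly known to the ledger.

Three generator choices exist purely to make the stated world's *object
boundaries* well-posed, so that noiseless truth recovery is exact rather
than approximate: clearing patches are radius-capped (the frontier advances
at most ~7 px per year) and keep a 3-pixel separation from still-visible
logging features; clearings never fall below the minimum mapping unit; and
tiny forest pockets stranded by a clearing are cleared with it. Without
these, region merging legitimately absorbs one-pixel forest slivers into
adjacent clearing objects and the "truth" becomes ambiguous at the object
level. What a green end-to-end test therefore establishes is that the
pipeline recovers a *consistent* landscape exactly and a noisy one within
tolerance — not that it resolves boundary ambiguities a real landscape
(mixed pixels, gradual regrowth, burning, clouds) would present. Real-scene
rules and thresholds still need per-scene tuning.

## Numerical choices

* Face enumeration makes the constrained unmixing exact to solver
  precision; candidate fractions are clamped at $-10^{-9}$ feasibility
  tolerance and renormalised.
* Segmentation ties break on segment ids (column-major pixel order); all
  stages are deterministic given config + seed, and re-runs are
  bit-identical (asserted in the test suite).
* Intensity of a forest-free cell is undefined (`NA`, class `NO_FOREST`),
  never 0, and rates with a zero forest denominator are reported missing.
* The sampling function saves and restores the global RNG state.

## Known limitations

* GeoTIFF/GeoPackage I/O is replaced by plain-text ESRI ASCII grids plus
  JSON sidecars (no GDAL-backed raster package is assumed); the in-memory
  contracts are unchanged.
* No atmospheric/BRDF correction, cloud masking, regrowth mapping, fire
  attribution, buffer-based affected-area delineation or NDFI — all out of
  scope by design.
* The default classification rules are tuned to the synthetic world's
  signatures and are starting points, not field-calibrated values.
* Area-weighted (stratified-estimator) accuracy with variances is not
  implemented; the matrices report naive counts, as the published tables
  do.
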