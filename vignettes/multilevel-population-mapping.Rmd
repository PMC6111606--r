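---
title: "Multi-level dasymetric population mapping: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level dasymetric population mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgrid)
library(dplyr)
```

## The problem

Census populations are reported per administrative unit — streets (the
fourth administrative level in Chinese cities) and communities (the fifth)
— while planning, epidemiology and accessibility analyses need population
on regular grids. popgrid redistributes unit censuses onto 250 m and 50 m
grids using classified residential building footprints as the ancillary
layer: people live in residential floor space, so footprint area is the
natural dasymetric weight. Building stock is classified into five classes:
multi-floor and low-floor buildings (large footprints, at least 1600 m²),
their "independent" small-footprint counterparts (at least 200 m²), and
abandoned buildings, which never carry population.

Two models are used, matched to the granularity of the census:

**District level (streets).** Within a district, residential houses of the
same class are assumed to share one population density. With street census
populations $y_i$ and per-class residential areas $S_{ki}$ on street $i$,
the no-intercept least-squares model

$$y_i = a_1 S_{1i} + a_2 S_{2i} + a_3 S_{3i} + a_4 S_{4i} + \Delta_i$$

estimates class densities $a_k$ (persons/m²). There is no intercept: a
street with no residential floor space houses nobody. If any estimated
coefficient is negative or not estimable, or the goodness of fit falls
below 0.5, the four classes are merged pairwise (multi + multi-independent;
low + low-independent) and the two-class model is refit — small-footprint
classes are often too rare for separate identification. Because fitted and
census populations still differ street by street, every class coefficient
is rescaled per street by the ratio of census to fitted population,
$a_k' = (y_i/\hat y_i)\,a_k$. This correction makes the subsequent
disaggregation conserve each street census exactly, by construction:
$\sum_k a_k' S_{ki} = y_i$.

**Street level (communities).** Communities are far smaller and their area
ranges narrow, so a regression across communities would be poorly
conditioned; instead each community gets one average density
$d_c = P_c / C1_c$, its census population over its residential house area.

**Grids.** Each residential building contributes its (corrected) density
times its area, apportioned to grid cells by exact polygon–cell
intersection-area fractions — not by centroid assignment — so per-unit grid
sums equal the censuses to float tolerance at both levels.

## Extraction completeness and augmentation

Survey attribution is imperfect: some buildings lack residential-quarter
(rq) or community attribution. Residential area extraction on a street
counts as *incomplete* when the rq-attributed share of building area is
below 20 % ($R1/R3 < 0.2$) **and** the share with no community attribution
exceeds 20 % ($R2/R3 > 0.2$); then community-attributed buildings without
rq attribution are also counted as residential and added to $R1$ and to
the design matrix. The analogous community rule fires when $C1/C2 < 0.2$
and the implied density $P/C1$ exceeds 1 person/m² (an implausible
residential density, signalling that $C1$ misses floor space). Threshold
comparisons are strict; equality counts as complete. All four thresholds
are configuration parameters with those defaults.

The source description of the street rule is worded ambiguously (the
sentence as printed would augment exactly when extraction is already
complete); popgrid implements the only self-consistent reading — ratios
meeting both conditions mean extraction is incomplete and augmentation is
applied — and exposes the thresholds in the configuration.

## Verification suite

* **Local Moran's I** per cell, $I_i = z_i \sum_j w_{ij} z_j / (\sum z^2/n)$,
  with row-standardised queen-contiguity weights by default, conditional
  permutation pseudo p-values (999 draws), and quadrant cluster labels
  (High-High, Low-Low, High-Low, Low-High) at $\alpha = 0.05$. None of
  these settings is prescribed by the method itself; all are configurable
  (rook contiguity, permutation count, $\alpha$). A constant surface
  yields all-zero $I_i$ and no labels rather than a division by zero.
* **Overlay statistics**: mean Euclidean distance from populated cells to
  the nearest point/line feature, by population class (deciles of nonzero
  cells by default, because the binning of "population levels" is
  analysis-specific), and multi-ring buffer coverage — for point features,
  ring growth by Chebyshev (8-neighbour) cell distance from the seed cells
  (rook growth available); for lines, Euclidean buffers at 50/100/150/200 m
  with a cell counted when its centre lies inside. Coverage is cumulative,
  non-decreasing and bounded by 100 %.
* **Cross-level comparison**: the 50 m grid is block-summed 5×5 to the
  250 m layout (origins shared by construction, totals conserved exactly)
  and compared cell-wise via the symmetric relative error
  $2(CS - SS)/(CS + SS) \in [-2, 2]$, binned into the standard report bins
  ($<-1$, $[-1,-0.8)$, …, $0$, …, $>1$). Cells empty on both levels are
  excluded and counted separately. Differences below $10^{-9}$ are binned
  as exact agreement, so float noise does not empty the "0" bin.

## The synthetic-city generator

No public release of the national-survey building layers exists, so the
package ships a generator that emulates their structure: axis-aligned
rectangular footprints on a lot/community/street partition of a rectangle
(rectangles keep every intersection-area oracle exact and fast), the
five-class taxonomy with size floors respected (40–60 m sides for the
large classes, 15–30 m for the independent ones), nested admin polygons,
and censuses equal to planted totals times multiplicative lognormal noise
(populations are positive and census errors plausibly proportional;
default sd 5 %). Streets differ in building stock through a lognormal tilt
of the category mix (sd 0.5) and a per-street lot-occupancy probability
drawn from 0.6–0.95 — without this between-street variation the design
matrix would be nearly constant across streets, which no real district is.
Abandoned buildings carry street attribution only, which is also the
mechanism that populates the street-only area vector $R2$.

Default planted densities are 0.11 / 0.09 / 0.05 / 0.04 persons/m² for the
four residential classes, in the range urban fits produce. Scenario
presets pin down the conditions each rule needs:

* `clean` — full attribution, no noise, one uniform density
  (0.08 persons/m²). Uniformity is deliberate: the street-level model
  estimates a single density per community, so only a within-community
  uniform truth lets *both* levels reproduce the truth grid cell by cell;
  that end-to-end identity is the scenario's purpose.
* `partial-rq` — rq coverage 7 %, abandoned share 40 % (by count), no
  noise: both completeness rules fire on every unit and augmentation must
  restore exact recovery of the (distinct) planted densities.
* `negative-coef` — each street's multi-floor-independent area is rescaled
  to exactly 0.4 × its multi-floor area, making the four-class design
  rank-deficient. A coefficient that is not estimable is treated as a
  merge trigger alongside negative coefficients and low fit quality: exact
  collinearity is the limiting case of the instability the merge rule
  exists for. The planted low-floor densities are equal, so the merged
  model is exact ($R^2 = 1$).
* `street-vs-district` — per-community lognormal density multipliers
  (sd 0.2, roughly a 20 % occupancy spread between communities, a
  realistic violation of the district-level uniformity assumption) plus 5 %
  census noise, so the two levels disagree and the cross-level error
  histogram has spread.

What passing on synthetic cities does **not** show: robustness to
irregular footprint and admin geometries, topology errors, or survey
attribute quirks; realistic urban morphology; or any statement about the
original survey data. The generator exercises the rules, not the city.

## Numerical choices and degenerate inputs

* Geometry is a small planar kernel (shoelace areas, Sutherland–Hodgman
  clipping against convex windows, ray-casting containment) over polygons
  in one projected CRS in metres; geographic coordinates are rejected
  rather than silently reprojected because areas in m² are load-bearing.
  Grid cells are half-open, so a point on a shared edge belongs to exactly
  one cell, and the grid origin is the data extent's lower-left corner
  snapped down to a cell-size multiple (deterministic, and it aligns the
  50 m and 250 m layouts).
* "Belonging to" an admin polygon is majority intersection area (≥ 50 % of
  the footprint), with ties broken by largest intersection then lowest
  unit id, and a representative-point fallback when all intersections are
  exactly zero. The source procedure says only "spatial location query";
  majority area is the documented choice because it is insensitive to
  boundary digitisation error on the scale of a building.
* Categories with all-zero area are dropped from the design matrix and
  reported as absent — they are missing data, not model degeneracy, and do
  not trigger the merge.
* $R^2$ is the centred goodness of fit of the no-intercept model; for a
  degenerate fit with zero centred variance and zero residuals it is
  reported as 1. The published fit statistics are reproduced only under a
  through-origin regression of fitted on census populations with
  centred-total-sum-of-squares goodness of fit; that is therefore the
  definition `evaluate_fit()` implements.
* A community with population but no residential area after augmentation
  aborts with an actionable error instead of silently spreading population
  over all building area; negative corrected coefficients likewise abort
  disaggregation rather than emitting negative population cells.
* The community-level area ratio divides community-summed $C1$ by the
  community total $C2$: the per-quarter form is not dimensionally
  consistent with a per-community denominator.

## Problem sizes

The shipped tests run cities of 6–14 streets with 3–6 communities each
(roughly 400–900 buildings), grids up to about 100 cells at 250 m and
2 500 cells at 50 m, permutation inference at 99–999 draws, and the
repeated-seed recovery study at 100 replicates of a 12-street city —
sizes chosen so the full suite exercises every rule in well under five
minutes while keeping all conservation checks at float tolerance.

## Known limitations

* Vector I/O is GeoJSON (plus CSV censuses and CSV/ESRI-ASCII grids);
  Shapefile and GeoTIFF are out of scope.
* Multi-part polygons and holes are not supported (holes are dropped with
  a warning); majority-area assignment assumes convex building footprints
  (exact for the rectangular synthetic stock).
* The merge fallback cannot rescue a model whose merged coefficients are
  still negative; such fits abort at disaggregation.
* No spatial regression variants (GWR), intercept models or weighting
  schemes — the density model is deliberately plain least squares.
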