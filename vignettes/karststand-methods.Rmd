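---
title: "Methods: stand structure and diversity on rock and soil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stand structure and diversity on rock and soil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karststand)
```

This vignette documents the models and conventions behind `karststand`:
what each quantity is, which choices were genuinely open and how we made
them, what the synthetic generator does and does not emulate, and the
numerical details a careful user should know.

## The analysis in one paragraph

A fully mapped plot (every standing live stem with coordinates, species,
DBH ≥ 1 cm, height, life form) is overlaid with a 10 m quadrat grid.
Digitized rock-outcrop polygons classify each quadrat as *rock* (rock
covers ≥ 50 % of the cell) or *soil*. Surveyed elevations at the quadrat
vertices and centers yield per-quadrat elevation, convexity, slope and
aspect. Diversity indices (R, N, H′, E_H), nearest-neighbour structure
parameters (W, U, M) and size metrics (DBH, TH, BA) are computed per
tree and per quadrat, then compared between site types
(Kruskal–Wallis), across structure-parameter distributions
(Kolmogorov–Smirnov) and along topographic gradients (OLS per site
type).

## Terrain from quadrat vertices

Quadrat elevation is the arithmetic mean of the four vertex elevations;
convexity is the center elevation minus that mean, so a bilinearly
interpolated center forces convexity to zero. For that reason center
elevations are an *input*: interpolation is only an explicit opt-in
fallback (`interpolate_centers = TRUE`) and is flagged per quadrat in
the output.

Slope is the mean dip angle of the four planes through any three of the
quadrat's vertices (`acos(|n_z|/‖n‖)` for plane normal **n**). For
aspect, two conventions had to be fixed because "mean angle to north"
is ambiguous:

* each plane's aspect is the bearing of its *downslope*
  (steepest-descent) direction, the GIS convention;
* the four per-plane aspects are combined by the **circular mean** —
  an arithmetic mean is simply wrong across the 0°/360° wrap (350° and
  10° average to 0°, not 180°).

Flat planes (dip < 1e-9°) have no aspect and are excluded; an all-flat
quadrat gets an `NA` sentinel, which downstream regressions drop. Slope
and convexity remain defined there.

Coordinates are plot-local Cartesian metres (x east, y north, origin at
the lower-left corner); azimuths are degrees clockwise from north. Cell
membership is half-open, `[lo, hi)`, with the top/right plot boundary
folded into the last cell, so every stem belongs to exactly one quadrat.

## Substrate classification

Rock cover per quadrat is the exact area of intersection between the
cell rectangle and the rock polygons, by Sutherland–Hodgman clipping
(exact for any simple polygon against a convex window) and the shoelace
formula. Rock polygons are assumed mutually disjoint — digitized outcrop
patches do not overlap — so areas add. The test suite cross-checks every
clipped fraction against an independent 0.1 m rasterization oracle to
within 0.01.

A quadrat is rock when its fraction is **≥** the threshold (default
0.5, configurable), soil otherwise, so a fraction of exactly 0.5
classifies as rock. Because quadrat-based areas (count × 100 m²) and
actual polygon areas differ, site-type summaries report densities under
*both* conventions rather than resolving the discrepancy.

## Structure parameters

Each reference tree is paired with its 4 nearest neighbours (exact
search; distance ties broken by stem id, so results are deterministic).
The indices use strict inequalities with ties scoring 0, following the
"smaller than" convention:

* **W**: sort the neighbour bearings, take the four circular gaps
  (summing to 360°), score gaps `< α₀`; a 0° gap (two neighbours at the
  same bearing) counts. α₀ defaults to 72° = 360°/(k+1) for k = 4, the
  standard-angle convention of the uniform-angle-index literature; it is
  configurable.
* **U**: neighbours strictly larger than the reference; DBH is the
  default size variable (TH and BA selectable). U = 1 means fully
  suppressed.
* **M**: neighbours of a different species.

Edge handling is genuinely underdetermined in field practice, so both
policies are emitted: every tree gets a record, trees within a 5 m
boundary buffer are flagged, and summaries either include them or (the
default, and what the calibration checks use) exclude them while still
letting them serve as neighbours of interior trees. There is no toroidal
wrapping. Neighbour search is stand-wide — it crosses quadrat
boundaries.

Under CSR the stand mean of W sits near 0.5; the package's calibration
check (see `scripts/acceptance.R`) simulates 20 Poisson stands of 2,000
stems in a 200 × 110 m window and compares the replicate grand mean
against the published random-pattern interval [0.475, 0.517].

## Diversity and size

`H′ = −Σ p_i ln p_i` and `E_H = H′ / ln S` use natural logarithms
throughout (mixed-base definitions appear in the literature; natural
logs make the two formulas consistent, with E_H = 1 at perfect
evenness). E_H is reported as an `NA` sentinel for S = 1 — not 0 or
1 — and excluded from summaries. Per-hectare densities are
`count · 10⁴ / area`; integer reports truncate toward zero (1,427 stems
on 6,224 m² prints 2,292/ha) and the raw value is retained.

Basal area is `π (DBH/200)²` m² with DBH in cm. "BA per quadrat" means
the mean per-tree basal area, with total BA per quadrat also emitted.
By Jensen's inequality mean BA ≥ BA(mean DBH), with equality only at
zero variance; the tests assert exactly that direction.

## Statistical comparisons

Kruskal–Wallis (`stats::kruskal.test`, tie-corrected, chi-square p) and
the two-sample KS test (`stats::ks.test`, asymptotic p) back the
comparison operations; the test suite verifies both against independent
oracles (the rank-sum formula, a Monte-Carlo permutation null, and
exhaustive ECDF evaluation). Quantized W/U/M samples are heavily tied:
the KS D statistic is exact but its asymptotic p value is approximate
there, which is documented rather than "fixed". Significance bands
follow the three-way convention (p ≥ 0.05 ns, 0.01 ≤ p < 0.05
significant, p < 0.01 highly significant) with boundary values assigned
to the less significant band. No multiple-testing correction is applied,
matching the analysis design this package scripts; users running many
comparisons should adjust externally.

Trends of metrics against topography are ordinary least squares per
site type — "linear relationship" is taken literally, though published
figure curves of this kind are sometimes loess. Aspect is regressed on
raw degrees by default (matching the field convention of plotting
against aspect 140–340°), with a sine/cosine decomposition available via
`aspect_components = TRUE` because raw degrees misbehave across the
0/360 wrap; the flag reports fit-level R² and p instead of a single
slope.

`ordination_export()` assembles the six explanatory variables (rock and
soil area within the quadrat, elevation, convexity, aspect, slope), the
response block (R, N, H′, E_H, W, U, M, DBH, TH, BA) and the
species-by-quadrat abundance matrix, aligned on quadrat id with sentinel
rows dropped. Fitting RDA/NMDS is deliberately out of scope — `vegan`
does it well — and no ordination results are computed here.

## The synthetic generator

The generator supplies test inputs with the statistical structure the
pipeline assumes. Its defaults describe the emulated old-growth karst
oak plot: 200 × 110 m (220 quadrats), 4,596 stems of 62 species with a
strongly skewed abundance distribution, 28.3 % rock cover, base
elevation 1,293 m, mean slope 25°, dip azimuth 200°.

* **Points**: Poisson (CSR), Thomas cluster (parents Poisson-many and
  uniform, offspring Gaussian with configurable spread, reflected into
  the window) or hard-core (sequential inhibition), all conditioned on
  the exact stem count so density-based metrics are comparable across
  patterns. Stems closer than 1 cm are rejected and redrawn — neighbour
  bearings are undefined at zero distance. Infeasible hard-core requests
  fail up front with the radius, count and window named.
* **Species**: the census preset lists 40 enumerated taxa plus 22 rare
  species; the pooled 28 rare individuals are expanded as 6 doubletons
  and 16 singletons to preserve both the total and the richness. Rare
  life forms were not recorded in the source census and default to
  "tree". Assignment uses exact largest-remainder multinomial counts by
  default (iid sampling optional), so at the census total the preset
  reproduces its table exactly.
* **Sizes**: DBH ~ Weibull(1.1, 5 cm) left-truncated at the 1 cm census
  threshold via the inverse CDF — shape ≈ 1 gives the reverse-J diameter
  distribution of uneven-aged stands; height follows
  `TH = 1.3 + 1.9 · DBH^0.55` m with mean-one lognormal noise
  (sdlog 0.15) on the increment, keeping TH > 1.3 m. The defaults put a
  3 cm sapling near 4.7 m and a 25 cm oak near 12 m, consistent with the
  emulated canopy.
* **Substrate**: disjoint star-shaped blobs (low-order harmonic
  perturbations of circles, 28 vertices) around rejection-sampled seeds,
  clipped to the plot; a common radius scale factor is bisected until
  the achieved fraction is within 0.005 of the target (guaranteed band
  ± 0.03), topping up with extra blobs when coverage cannot be reached
  by scaling alone.
* **Elevation**: the planar trend (base at plot center, dipping
  tan(25°) along azimuth 200°) plus a stationary harmonic Gaussian noise
  field (48 random cosine components, correlation length 40 m,
  sd 1.5 m). With sd = 0 the field is exactly planar — which is what
  makes the terrain identities testable: convexity ≡ 0, slope ≡ 25°,
  aspect ≡ 200° for every quadrat.

One global seed drives four independent sub-streams (points, marks,
substrate, elevation), so each component regenerates identically on its
own; scenarios serialize byte-identically (all numeric output is written
at 9 significant digits).

**What the generator does not emulate.** Species placement is
independent of substrate and of conspecifics by default (an optional
rock-affinity thinning is the only association mechanism), so generated
stands show random-labelling mingling (`M ≈ 1 − Σ p_i²`, about 0.83 for
the census abundances) rather than the lower values of field stands with
conspecific clustering; there is no size–habitat interaction, no
succession, and no deadwood. Passing tests therefore demonstrate that
the *pipeline* is correct and calibrated (e.g. W under CSR), not that
field-specific values such as site-wise mingling means are reproduced —
those depend on the undeposited census itself.

## Problem sizes and numerical details

The test suite runs the CSR calibration at its full size (20 × 2,000
stems), the analytic-moment and abundance-recovery checks at n = 10⁵
draws, pattern-ordering at 6 replicates per process, brute-force k-NN
oracles at n = 500, raster cross-checks on sampled quadrats of several
scenarios, and the end-to-end demo scenario at 1,200 stems — sizes
chosen to exercise every code path at meaningful statistical power while
keeping the default suite quick on one CPU.

Other numerical choices: quadrat divisibility is checked to 1e-9 m;
flat-plane detection at 1e-9°; circular means fold bearings within
1e-9° of 360 back to 0; the polygon clipper may emit zero-area connector
edges for multi-piece intersections, which the shoelace area ignores by
construction; Kruskal–Wallis on fully identical samples returns H = 0,
p = 1 rather than the 0/0 of the tie-correction formula.

## Known limitations

* Substrate polygons must be simple and pairwise disjoint; overlapping
  rock patches would overcount area (inputs are validated for
  simplicity, not disjointness).
* Hard-core generation is sequential inhibition, which becomes slow near
  the jamming density; requests beyond a conservative feasibility screen
  error immediately.
* The KS p value on quantized inputs is approximate (ties); the D
  statistic is exact.
* Aspect enters linear trends in raw degrees by default; use the
  sine/cosine flag near the north wrap.
* No geodetic CRS handling: all coordinates are plot-local metres.
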