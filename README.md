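# karststand

Quadrat-based stand-structure and diversity analysis for fully mapped
forest plots on karst terrain.

Karst landscapes interleave exposed rock outcrops with pockets of soil,
and the two substrates can carry very different tree communities. Given a
stem map (every standing live tree with coordinates, species, DBH ≥ 1 cm,
height and life form), digitized rock-outcrop polygons, and surveyed
elevations at quadrat vertices and centers, `karststand` answers the
standard questions of this literature: how do species diversity, spatial
structure and tree size differ between rock and soil sites, and how do
they respond to topography?

The package is aimed at forest ecologists working with mapped plots
(10 m quadrat grids) who want a scripted, reproducible version of this
analysis, including a synthetic-stand generator so the entire pipeline can
be exercised and tested without access to field data.

## What it computes

**Terrain, per 10 m quadrat** (from the four vertex elevations `z1..z4`
and the center elevation `zc`):

- elevation = mean(z1..z4)
- convexity = zc − mean(z1..z4)
- slope = mean dip angle of the four planes through any three vertices,
  where a plane with normal **n** dips at `acos(|n_z| / ‖n‖)`
- aspect = circular mean of the downslope bearings of those planes
  (degrees clockwise from north; flat planes excluded)
- site type: *rock* when the clipped rock-polygon area covers ≥ 50 % of
  the quadrat, else *soil*

**Species diversity** (per plot, site type, or quadrat), with
`p_i = n_i / N`:

- richness `R = S`, abundance `N`
- Shannon–Wiener `H′ = −Σ p_i ln p_i`
- Pielou evenness `E_H = H′ / ln S` (undefined at `S = 1`)
- stem densities per hectare under both area conventions (actual
  substrate area, and quadrat count × cell area)

**Stand spatial structure parameters**, per reference tree `i` from its 4
nearest neighbours `j`, each quantized to {0, ¼, ½, ¾, 1}:

- uniform angle index `W_i = ¼ Σ z_ij`, `z_ij = 1` when the j-th circular
  gap between consecutive neighbour bearings is smaller than the standard
  angle α₀ = 72°; ≈ 0.5 under complete spatial randomness (CSR)
- dominance `U_i = ¼ Σ k_ij`, `k_ij = 1` when neighbour j is larger than
  the reference (DBH by default)
- mingling `M_i = ¼ Σ v_ij`, `v_ij = 1` when neighbour j is a different
  species

**Tree size**: DBH, height, and basal area `BA = π (DBH/200)²` m²
(DBH in cm), averaged per quadrat and site type.

**Comparisons**: Kruskal–Wallis rock-vs-soil tests on quadrat-level
metrics, two-sample Kolmogorov–Smirnov tests on structure-parameter
distributions, per-site-type linear trends against topography, and
export of aligned response/explanatory/abundance matrices ready for
RDA/NMDS in `vegan` (the ordinations themselves are out of scope).

The synthetic generator draws stands under Poisson (CSR), Thomas-cluster
or hard-core point processes with skewed species abundances, truncated
Weibull diameters, allometric heights, blob-shaped rock maps hitting a
target cover fraction, and planar-plus-noise elevation fields.

## Worked example

```r
library(karststand)

cfg <- stand_config(seed = 1)   # census preset: 4,596 stems, 200 x 110 m
sc  <- simulate_stand(cfg)
#> Synthetic stand scenario: 4596 stems, 62 species, 220 quadrats
#>   rock fraction 0.283; pattern 'poisson'; seed 1

terrain <- terrain_table(sc$grid, sc$elevations, sc$substrate)
site_type_totals(terrain)[1:2]
#> $n_rock_quadrats
#> [1] 54
#> $n_soil_quadrats
#> [1] 166

div <- diversity_table(sc$stems, sc$grid, terrain, sc$substrate)
div$site_type[, c("site_type", "N", "R", "shannon", "evenness",
                  "density_substrate_ha")]
#>   site_type    N  R shannon evenness density_substrate_ha
#> 1      rock 1153 39   2.172   0.5930                 1851
#> 2      soil 3443 58   2.233   0.5499                 2182

rec <- sssp_table(sc$stems, sc$grid, terrain)   # W, U, M per tree
subset(group_summaries(rec)$groups, lifeform == "all")
#>   site_type lifeform    n     W     U     M
#> 1       all      all 3979 0.481 0.499 0.832
#> 2      soil      all 3041 0.482 0.497 0.834
#> 3      rock      all  938 0.475 0.507 0.827

kruskal_wallis(split(div$quadrat$shannon, div$quadrat$site_type))
#> Kruskal-Wallis: statistic = 0.2546, p = 0.6139 (ns), n = 54/166
```

Reading the output: 54 of the 220 quadrats classify as rock under the
≥ 50 % rule. Both site types have Shannon diversity near 2.2 and mean
uniform angle index near 0.48 — the CSR signature, as expected for a
Poisson-generated stand — and the Kruskal–Wallis test finds no
rock-vs-soil diversity difference, which is the correct null answer for
this scenario: the generator placed species independently of substrate.
Mean mingling (≈ 0.83) equals the random-labelling expectation
`1 − Σ p_i²` for the census abundances; field stands with conspecific
clustering sit lower.

`run_pipeline(cfg, "out/")` runs every stage and writes all tables as
provenance-stamped CSVs; `inst/cli/karststand.R` wraps it for shell use.

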