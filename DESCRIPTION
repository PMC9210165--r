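Package: karststand
Title: Stand Structure and Diversity Analysis of Karst Forest Plots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quadrat-based analysis of fully mapped forest plots on karst
    terrain. Builds a 10 m quadrat grid, derives per-quadrat topographic
    attributes (elevation, convexity, slope, aspect) from surveyed vertex and
    center elevations, classifies quadrats as rock or soil from digitized
    rock-outcrop polygons, computes species diversity indices (richness,
    abundance, Shannon-Wiener, Pielou evenness), per-tree nearest-neighbour
    stand spatial structure parameters (uniform angle index, dominance,
    mingling), and tree-size metrics (DBH, height, basal area), and compares
    rock versus soil communities with Kruskal-Wallis, Kolmogorov-Smirnov and
    linear-trend analyses. Includes a synthetic stand generator (Poisson,
    Thomas cluster and hard-core point processes; skewed species abundances;
    Weibull diameters; blob substrate maps; planar-plus-noise elevation
    fields) so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
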