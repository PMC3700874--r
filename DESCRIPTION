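Package: mahomet
Title: Thermodynamic Energetics and Microbial Community Structure of a
    Methanogenic Aquifer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for linking groundwater geochemistry to subsurface
    microbial community structure, modelled on the Mahomet aquifer
    (east-central Illinois).  Ingests well chemistry tables with censored
    ("< limit") and missing entries, classifies wells by sulfate into
    high/low/negligible (HS/LS/NS) zones, and computes the energy
    available to anaerobic respiration (hydrogenotrophic sulfate
    reduction, methanogenesis, anaerobic methane oxidation, iron
    reduction) from in situ concentrations using an embedded
    thermodynamic registry, Gibbs-Helmholtz temperature correction and
    extended Debye-Hueckel activity coefficients.  Includes 16S rRNA
    clone-library utilities (97% average-neighbour OTU clustering,
    collector's curves, rarefaction, shared-richness accounting),
    community comparison statistics implemented from their definitions
    (Bray-Curtis, ANOSIM with permutation inference, SIMPER, non-metric
    multidimensional scaling with Kruskal stress), and seeded synthetic
    generators for chemistry tables, clone libraries and OTU count
    matrices so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
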