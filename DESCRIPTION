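Package: divgrad
Title: Herb-Layer Diversity Along Elevation and Forest-Use Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Hierarchical diversity analysis for site-by-species
    presence/absence data collected in a nested landscape design (locations
    along an elevational gradient, forest-use habitats within locations,
    replicate plots within habitats). Provides plot-level alpha richness and
    pooled gamma richness, pairwise Sorensen-based beta diversity with
    within- and between-habitat comparison schemes and bootstrap standard
    errors, multiplicative alpha-beta-gamma partitioning, empirical and
    asymptotic Hill-number diversity profiles for incidence data, and
    AICc-ranked generalized linear models with response-appropriate error
    families. A synthetic-landscape generator reproduces the statistical
    structure the analysis assumes, so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    glmmTMB,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'IncidenceExperiment-methods.R'
    'utils.R'
    'beta.R'
    'divgrad-package.R'
    'richness.R'
    'glm.R'
    'hill.R'
    'io.R'
    'partition.R'
    'simulate.R'
    'pipeline.R'
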