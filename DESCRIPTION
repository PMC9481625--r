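Package: alleleNiche
Title: Genic Distribution Modelling of Allelic Climatic Niches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-entropy presence/background niche models applied to
    intraspecific genetic variants (genic distribution modelling). Fits
    per-allele MaxEnt-style models with linear, quadratic, product and hinge
    features, L1 regularization and AICc tuning; evaluates them with AUC,
    partial-AUC ratios and subsampling replicates; selects climate variables
    by reiterative jackknife and correlation filtering; quantifies niche
    overlap between two alleles with Schoener's D in geographic and
    environmental space, with niche-identity and background-similarity
    randomization tests; and projects relative climatic favourability under
    altered climate scenarios. Includes a synthetic-world generator with
    known Gaussian niche truth for validation, and ESRI ASCII grid and
    delimited-text I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ascii-grid.R'
    'grid-geometry.R'
    'climate-stack.R'
    'utils.R'
    'extract.R'
    'features.R'
    'maxent-fit.R'
    'maxent-predict.R'
    'evaluation.R'
    'methods-accessors.R'
    'occurrences.R'
    'overlap.R'
    'serialize.R'
    'projection.R'
    'pipeline.R'
    'synthetic-world.R'
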