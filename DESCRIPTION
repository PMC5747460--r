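Package: invasiontrace
Title: Retracing Multi-Origin Biological Invasions from Historical First
    Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for retracing the introduction and spread of an invasive
    species from dated, georeferenced historical occurrence records.
    Implements earliest-record ("first report") extraction per territorial
    unit, diachronic filtering, K-means partitioning with Silhouette-based
    selection of the number of invasion clusters, per-cluster geographic
    profiling (Rossmo criminal-geographic-targeting probability surfaces)
    to locate probable introduction areas, Voronoi territory assignment,
    and chloroplast-microsatellite (cpSSR) haplotype calling with
    per-population frequency summaries. A ground-truth-known simulator of
    multi-origin invasions and of cpSSR genotype samples supports recovery
    testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    geosphere,
    jsonlite,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils-geometry.R'
    'clustering.R'
    'geoprofile.R'
    'haplotypes.R'
    'invasiontrace-package.R'
    'records.R'
    'pipeline.R'
    'synthetic.R'
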