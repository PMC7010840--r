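Package: endosurvey
Title: Community Analysis of Culturable Endophytic Fungus Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segment-based isolation surveys of culturable
    endophytic fungi: survey metrics (colonization rate, richness, relative
    abundance) with the usual univariate comparison battery, constrained
    ordination (canonical correspondence analysis) and distance-based
    PermANOVA implemented from first principles, and permutation-based
    host/tissue preference statistics (standardized d' interaction
    specialization and two-dimensional preference z-scores with false
    discovery rate control). Includes a synthetic survey generator that
    emulates a multi-host, multi-tissue isolation design with controllable
    colonization probabilities and taxon preference weights, so every stage
    of the pipeline can be exercised against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
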