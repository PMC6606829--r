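Package: sludgecycle
Title: Genome-Centric Time-Series Analysis of Microbial Disturbance Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-resolved analysis of metagenomic time series
    from engineered ecosystems such as activated sludge. Estimates per-genome
    rRNA (rrn) operon copy numbers from the ratio of 16S rRNA gene coverage to
    genome coverage, computes in situ replication indices (iRep-style
    peak-to-trough ratios) from genome-wide coverage gradients, builds
    co-occurrence networks by local similarity analysis with permutation
    significance, and derives consensus disturbed/stable operational periods
    by intersecting self-organizing-map sample clusterings of genome and
    functional-module abundances. Includes a synthetic community generator
    with known ground truth (copy numbers, replication rates, regime
    structure) so that every estimator has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    nortest,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
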