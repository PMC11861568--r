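Package: lumiscreen
Title: Analysis of Luminescent Arrayed siRNA Screens with Expression,
    Enrichment and Phosphoproteomic Companions
Version: 0.1.0
Authors@R:
    person("Screen", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for arrayed RNA-interference
    high-throughput screens read out by luminescence: plate-by-plate
    normalization against negative-control wells, per-replicate Z-scoring,
    replicate aggregation and strict threshold hit calling into activator
    and inhibitor classes. Companion stages restrict the screened library
    to transcribed genes via a read-count median rule, score hit lists
    against GMT gene-set libraries (Fisher exact test, Benjamini-Hochberg
    adjustment, combined score from the rank-deviation z), and call
    differentially regulated phosphosites from TMT intensity tables
    (confidence filters, median-centered log2 intensities, two-sample
    t-test with a dual significance threshold). A synthetic-data module
    generates screens, count tables, gene-set libraries and phosphosite
    tables with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
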