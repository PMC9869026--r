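Package: hifimag
Title: Genome Recovery and Community Profiling from HiFi Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for recovering microbial genomes from PacBio HiFi
    metagenome assemblies and for profiling the underlying community.
    Includes assembly-graph topology triage of GFA files (circular,
    tangled-circular and linear contigs), single-copy-marker completeness
    and contamination scoring with quality ranks, MinHash/ANI based
    dereplication of candidate genomes, novelty assessment against a
    reference catalog, coverage-depth community composition, and
    amplification-free full-length 16S rRNA gene profiling directly from
    reads with copy-number correction.  A synthetic-community simulator
    with a machine-readable truth manifest makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
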