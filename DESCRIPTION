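Package: lncanalog
Title: Cross-Species Screening for Functionally Convergent Long Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate functionally convergent (analogous) long
    noncoding RNAs across species that share k-mer content and secondary
    structure while lacking linear sequence homology. Implements
    background-standardized k-mer profile correlation with percentile
    gating and reciprocal screening, a transparent ORF/Fickett
    coding-potential filter, secondary-structure profile comparison by
    open-begin-end dynamic time warping with dinucleotide-shuffle null
    distributions, dotplot and sliding-window identity analyses for
    linear-homology exclusion, and the qPCR arithmetic used to quantify
    candidate expression (delta-delta-Ct, standard curves, copies per
    cell, nuclear fraction). Seeded synthetic-data generators make the
    full screen testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
SystemRequirements: ViennaRNA (RNAplfold on the PATH) for the default
    structure-profile backend
Config/testthat/edition: 3
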