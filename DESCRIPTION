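Package: orthoselect
Title: Selection Scans on Ortholog Clusters of Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting positive selection in clusters of
    orthologous coding sequences from closely related species.
    Implements codon-aware alignment with a divergence filter, branch-model
    dN/dS inference under a GY94-style codon substitution model (one-ratio
    and free-ratio fits compared by likelihood-ratio test with FDR control),
    a codon-level McDonald-Kreitman test driven by read-depth and
    allele-count data, a physicochemical amino-acid property divergence test
    with sliding-window goodness-of-fit statistics, consensus calling across
    the three methods, and dual-set GO term enrichment. A codon sequence
    simulator with branch-specific omega, within-species polymorphism and
    planted GO enrichment makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    seqinr,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
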