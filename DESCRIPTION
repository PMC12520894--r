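Package: ccdriver
Title: Driver-Gene Discovery in Cumulus-Cell Transcriptome Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a driver-gene discovery workflow for grouped
    transcriptome profiles: differential-expression calling with fold-change
    and ANOVA p-value gates plus Benjamini-Hochberg correction, annotation
    filtering, construction of DEG interaction networks from a user-supplied
    interactome, topology and scale-free diagnostics, MCODE-style dense-module
    detection, consensus hub calling over twelve node-centrality coefficients,
    interquartile-range/Grubbs detection of highly modulated outlier genes,
    shared-versus-distinctive driver partitioning across pairwise comparisons,
    an individual-gene fallback for comparisons with too few DEGs to support
    network analysis, and delta-delta-Ct relative quantification for qPCR
    validation. A seeded synthetic-data generator produces expression
    matrices, annotation tables and interactomes with planted ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
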