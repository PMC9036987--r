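Package: phycosignal
Title: Detection and Network Analysis of Algal-Bacterial IAA Signaling
    Genes in Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for detecting indole-3-acetic acid
    (IAA) signaling genes in algal-bacterial community metagenomes:
    construction of a non-redundant, subtype-labelled protein reference
    database by greedy identity clustering; translated six-frame homology
    screening of short reads with Smith-Waterman alignment and
    Karlin-Altschul E-values; RPKM quantification of gene subtypes;
    genus-level lowest-common-ancestor taxonomic binning with min-score,
    top-percent and min-support filters; and thresholded Spearman
    co-occurrence networks between bacterial and phytoplankton genera,
    including degree-based and current-flow network metrics and the
    signaled positive-edge fraction statistic. A deterministic synthetic
    community generator provides planted-truth fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
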