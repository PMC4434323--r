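Package: pbmotif
Title: Protein Binding Microarray Motif Derivation, Cataloguing and
    Composite-Motif Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for turning protein binding microarray (PBM) probe
    intensities into 8-mer E- and Z-score binding statistics and position
    weight matrices (PWMs); extending motif coverage by DNA-binding-domain
    homology; organising motif collections by information-content weighted
    clustering and rule-based curation; and interpreting motifs via
    stereospecific composite-motif detection in ChIP-seq peak sets and
    motif-enrichment statistics in yeast one-hybrid bait and promoter/gene-set
    collections. Includes a synthetic-data module that emulates
    complete-coverage k-mer array designs, peak sets with planted composite
    motifs, bait sets and promoter collections, so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
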