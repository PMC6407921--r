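Package: preclip
Title: eCLIP Cluster Calling and PUMILIO Target Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An input-normalized cluster caller for eCLIP data and the
    downstream PUMILIO-target analyses built on it: UMI-based PCR-duplicate
    removal, per-nucleotide coverage and candidate-bin detection, normalized
    IP/input fold-change thresholding with replicate reproducibility
    filtering and overlap merging, PUMILIO response element (PRE) motif
    scanning, FPKM-normalized per-gene target occupancy, matched non-target
    selection, and Kolmogorov-Smirnov comparison of fold-change cumulative
    distributions. Includes a synthetic-data generator that emulates a
    two-genotype, two-replicate CLIP experiment with paired size-matched
    inputs, planted PRE sites, a dominant noncoding super-target, and
    negative-binomial RNA-seq counts with genotype-dependent repression of
    target genes, so every stage of the pipeline is testable against a known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
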