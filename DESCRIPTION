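Package: chipregulon
Title: ChIP-Seq Peak Concordance, Promoter Annotation and Motif Discovery
    for Bacterial Regulons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of bacterial transcription-factor ChIP-seq
    experiments on gene-dense genomes: simplified kernel-density peak calling
    with a control-partition false-positive-rate estimate, replicate peak
    concordance filtering by mutual nearest neighbours, annotation of peaks
    relative to predicted translation start codons with operon-aware promoter
    windows, a Monte Carlo randomized-placement null, Fisher's exact
    functional-category and gene-list enrichment, and EM (one occurrence per
    sequence) motif discovery with degenerate IUPAC consensus scanning. A
    synthetic-data generator with recorded ground truth exercises the whole
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomeInfoDb,
    ggplot2,
    IRanges,
    GenomicRanges,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
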