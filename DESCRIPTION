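Package: dartseq
Title: Deamination-Based m6A Site Calling for DART-Seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for mapping N6-methyladenosine (m6A) from DART-seq
    experiments, in which an APOBEC1-YTH (C-to-U) or ADARcd-YTH (A-to-I)
    fusion deposits editing events adjacent to methylated adenosines.
    Builds per-position nucleotide count matrices from aligned reads,
    calls edit sites enriched over a control condition using coverage,
    edit-ratio, fold-enrichment and minimum-edit thresholds, applies
    replicate-concordance, RAC-motif and deaminase-alone blacklist
    filters, and characterises site sets with metagene profiles,
    distance-to-reference histograms with a within-exon shuffle null,
    rank-sum comparisons of edit ratios and gene-set overlaps. A
    synthetic-data generator provides ground-truth genomes, annotations,
    pileups and alignments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    yaml,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
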