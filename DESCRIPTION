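Package: repeatscape
Title: Genomic and Epigenomic Analysis of Repetitive Regions from Long-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tumor/normal long-read sequencing analysis of repetitive
    genomic regions: consensus somatic structural-variant calling from multiple
    callers with breakpoint-tolerant matching, mutational-signature refitting by
    non-negative least squares (SBS96 and SV32 catalogs), binned read-coverage
    and CpG-methylation profiling over centromeric satellite and transposable-
    element annotations with PCA, Ward clustering and group statistics, and
    haplotype-resolved classification of promoter-region (THOR) methylation.
    Includes seeded synthetic-data generators that emulate every input format
    (bedMethyl, depth tracks, multi-caller SV VCFs, mutation catalogs, phased
    CpG calls) so the full pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    car,
    mclust,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
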