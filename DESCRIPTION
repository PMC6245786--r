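Package: homozymap
Title: Homozygosity-Based Linkage Mapping of Recessive Mutations from
    Pooled Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Mapping-by-sequencing of recessive point mutations from two
    phenotype-sorted offspring pools (mutant and sibling) genotyped at
    shallow coverage.  Implements per-chromosome homozygosity scores,
    a windowed homozygosity/heterozygosity ratio smoothed by locally
    weighted (tricube) regression, critical-region extraction around the
    smoothed maximum, genotype-pattern extraction of linked variants,
    transcript-model consequence annotation with impact rating, and a
    known-site / impact candidate-reduction cascade.  A Mendelian F2
    incross simulator with a Haldane recombination model and a binomial
    read-count genotype caller generates pool-seq variant tables so the
    whole pipeline is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    ggplot2,
    grDevices,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
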