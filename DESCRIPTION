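Package: mesnp
Title: Classification and Methylation-Concordance Analysis of CpG-Disrupting SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for identifying SNPs that create, destroy or displace CpG
    dinucleotides (meSNPs), detecting CpG islands under relaxed and strict
    length/GC/observed-expected criteria, testing meSNP enrichment inside
    genomic feature sets with a chi-square goodness-of-fit statistic, deriving
    group-specific hypermethylated regions from per-sample methylation peak
    sets, and filtering candidate epigenetic polymorphisms whose allele
    frequencies are concordant with the methylation phenotype. Includes a
    seeded synthetic-data generator (genome, variants, genotyped cohorts and
    peak sets) so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
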