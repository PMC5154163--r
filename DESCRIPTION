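Package: regsnv
Title: Detection of Regulatory SNVs in Transcription-Factor Binding Sites from ChIP-seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes single-nucleotide variants that alter transcription-factor
    binding motifs inside ChIP-seq binding sites. Computes exact position-weight-matrix
    (PWM) log-odds score distributions by dynamic programming, scores reference and
    alternative alleles, and compares their p-value ratio against a null distribution
    of ratios to nominate regulatory SNVs (regSNVs). Builds k-of-n consensus binding
    sites across ChIP-seq datasets, filters variant calls on depth and quality,
    annotates variants with genomic context and neighboring genes, tests
    allele-specific binding by chi-square, and associates carrier genotype with
    neighboring-gene expression using Mann-Whitney tests with Benjamini-Hochberg
    correction. Includes a seeded synthetic-fixture generator with planted signal
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    Biostrings,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicRanges,
    jsonlite,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
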