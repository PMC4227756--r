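Package: numtcaller
Title: Discovery, Genotyping and Dating of Polymorphic Nuclear Insertions of Mitochondrial Origin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects non-reference nuclear insertions of mitochondrial origin
    (NumtS) from paired-end whole-genome alignments by clustering
    mitochondria-anchored read pairs, refining breakpoints with soft-clipped
    reads, and scoring candidate sites with a genotype-likelihood model.
    Includes cohort-wide genotyping with EM-estimated population allele
    frequencies, permutation-based enrichment tests of insertion positions
    against genomic feature tracks, insertion dating from diagnostic
    ancestral/modern mitochondrial differences, screening of Numt variants
    against reported heteroplasmy positions, and a deterministic read-pair
    simulator that implants mitochondrial fragments into a synthetic diploid
    genome for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rsamtools,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
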