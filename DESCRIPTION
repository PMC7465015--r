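Package: retroseek
Title: Discovery and Characterization of Polymorphic Gene Retrocopies from
    Paired-End Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects intronless gene retrocopies (processed pseudogenes) from
    discordant paired-end read alignments over a parental gene locus,
    localizes insertion sites by clustering trans-mapping mates, and
    characterizes insertion breakpoints: target site duplication (TSD)
    detection, insertion-site G/C content, L1 endonuclease motif scanning,
    conserved-element context, and UTR truncation. Retrocopy sequences are
    compared against parental-gene population haplotypes to separate
    haplotype-derived variants from retrocopy-specific mutations, and
    in-silico PCR plus cohort allele-frequency summaries support population
    genotyping. A deterministic simulator generates synthetic genomes with
    planted retrocopy insertions and paired-end alignments so that every
    stage is verifiable against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
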