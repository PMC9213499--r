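Package: minkseg
Title: Segregation Filtering and Two-Locus Analysis for Mink Coat-Colour Variant Discovery
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping Mendelian coat-colour traits in farmed American
    mink from whole-genome variant calls. Implements a case-unique homozygous
    segregation filter over multi-sample genotype matrices, a minimal
    strand-aware coding-consequence annotator emitting HGVS-style c. and p.
    descriptions, Haldane-corrected odds-ratio association statistics with
    Wald inference and a Fisher exact alternative, a two-locus
    genotype-to-phenotype rule engine for the COPA Black crystal and MITF
    Hedlund white epistatic interaction, and a synthetic-cohort generator
    (VCF, GFF3, FASTA, phenotype tables) so the whole pipeline can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
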