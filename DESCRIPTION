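Package: dsRNAtools
Title: Detection and Quantification of Double-Stranded RNA Signatures in
    Transcriptome Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An integrated pipeline for characterising double-stranded RNA
    (dsRNA) in bulk transcriptome sequencing experiments. Detects A-to-I RNA
    editing sites from per-position pileups with replicate-consistency and
    ADAR-null control filtering, merges sites into edited regions and compares
    region-level editing frequencies between genotypes with a two-proportion
    z-test. Annotates dsRNA-forming potential of transcripts (antisense gene
    overlap, intronic inverted repeats, UG repeats, repeat-element overlap),
    analyses dsRNA immunoprecipitation (IP) experiments for IP-versus-input
    enrichment and between-genotype differential IP, and provides the shared
    statistical kernel (hypergeometric tails, chi-square, two-proportion
    z-test, Benjamini-Hochberg FDR). A fully deterministic synthetic-data
    generator emits genomes, annotations, pileups and count tables with a
    machine-readable truth table so every stage has parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
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
    rtracklayer,
    Rsamtools,
    SummarizedExperiment,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'core-io.R'
    'stats-kernel.R'
    'simulate.R'
    'editing-caller.R'
    'editing-stats.R'
    'structure.R'
    'ip-enrichment.R'
    'pipeline.R'
    'dsRNAtools-package.R'
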