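Package: qpcrdesign
Title: Splice-Variant-Aware qPCR Assay Design with Specificity and SNP Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end design of quantitative PCR assays from a genome,
    transcriptome, gene annotation and variant catalogue. Candidate primer
    pairs are generated per target transcript under product-size, placement
    and melting-temperature constraints (nearest-neighbour thermodynamics
    with Owczarzy monovalent-salt correction), screened for off-target
    amplification across the whole transcriptome, screened for known
    polymorphisms inside the genomic primer-binding regions, scored for
    hairpin and primer-dimer minimum free energy with DNA parameters at
    annealing temperature, grouped by the subset of splice variants each
    pair amplifies, and reduced to one assay per splice-variant category by
    maximum dimer MFE. A seeded synthetic-reference generator (multi-exon
    genes, exon-skipping isoforms, decoy paralogs, planted SNVs) provides
    ground truth for every screening stage, and a run-statistics module
    exports candidate/discard tallies, melting-temperature-difference and
    MFE distributions, and target-length outcome curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    parallel,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
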