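Package: MetaGlyco
Title: Quantification of Microbial Glycan Utilisation from Long-Read
    Metagenomes, Metatranscriptomes and Glycan Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying carbohydrate utilisation in marine
    microbial communities from long-read (HiFi) metagenomes,
    metatranscriptomes and glycan microarrays. Implements two-stage
    last-common-ancestor taxonomic classification of protein-alignment
    hits (gene level, then read level), genome-equivalent normalisation
    based on sixteen single-copy ribosomal protein (SC-RBP) marker
    genes, species estimation by identity clustering of four marker
    genes, truncated-average-depth (TAD) genome abundance, transcripts
    per million (TPM) with community-level denominators, MAG relative
    transcription via SC-RBP TPM ratios, rule-based detection of
    polysaccharide utilization loci (PULs), per-genome-normalised
    CAZyme family profiles, and glycan microarray signal processing
    (dataset-maximum normalisation, antibody retention filtering,
    replicate averaging and extraction summing). Seeded generators
    produce synthetic communities with known ground truth so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    IRanges,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
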