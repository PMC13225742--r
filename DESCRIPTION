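Package: abequant
Title: Quantification of Adenine Base Editing and Genome-Wide Off-Target SNVs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing adenine base editors from targeted
    amplicon sequencing and paired whole-genome comparisons. Quantifies
    per-position A-to-G editing profiles, editing windows (30%-of-peak
    rule), bystander and C-editing purity ratios and perfect-edit read
    fractions from amplicon reads; performs paired edited-versus-control de
    novo SNV calling with three-profile consensus, replicate overlap,
    guide-similar site enumeration and group statistics in the style of
    genome-wide off-target assays; classifies SNV sets into substitution
    spectra with strand-standardized flanking-context matrices, sequence-logo
    information content and TA/UA motif fractions; and generates fully
    synthetic genomes, reads and pileups with known ground truth so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    yaml
Config/testthat/edition: 3
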