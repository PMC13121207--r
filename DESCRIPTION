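Package: asorescue
Title: ASO Rescue-Set Proteomics, Founder-Haplotype and Splice-Variant
    Prioritisation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational stages of an antisense-oligonucleotide
    (ASO) splice-correction rescue study: per-feature differential abundance
    on log2 proteomic and phosphoproteomic matrices (Welch or pooled t,
    Benjamini-Hochberg q-values, per-feature z-scores); classification of an
    "ASO-T Rescue Set" of disease-altered, treatment-responsive features that
    shift back toward control levels without off-target effects, with a
    restoration-fraction label; over-representation analysis reporting
    RichFactor and InTerm metrics and KSEA-style inferred kinase activity;
    runs-of-homozygosity detection, founder-haplotype sharing with genotype
    quality filtering, a Somalier-style relatedness screen, and a splice
    variant prioritisation filter combining population frequency, SpliceAI
    delta scores, trio segregation, gene-list tiers and splice-outlier
    proximity; qPCR relative quantification against the geometric mean of
    reference genes; and synthetic-data generators that plant machine-readable
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
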