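Package: senescreen
Title: Natural-Variation Screen for Senescence-Dependent Transcription-Factor Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A tested, reusable pipeline for screening transcription factors
    whose activity changes with cellular senescence, using natural
    cis-regulatory variation between species. Allele-specific expression in
    interspecies F1-hybrid fibroblasts is tested gene-by-gene for a
    senescence-by-allele interaction (two-factor ANOVA); genes in the top
    quartile of interaction F are called senescence-dependent differential
    ASE, and per-factor 2x2 contingency tables of (binding-site variant
    presence x differential ASE) over 5-kb-upstream target genes are screened
    with Fisher's exact test and Benjamini-Hochberg correction. Includes TPM
    normalization, a resampling-based directional gene-set enrichment
    statistic, variant-position density profiles, and a synthetic-data
    generator with planted cis-by-condition effects for end-to-end
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
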