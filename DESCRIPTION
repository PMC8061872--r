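Package: hetage
Title: Sex- and Age-Resolved Heterochromatin and Repeat Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-level H3K9me3 ChIP enrichment with spike-in aware
    normalization, differential heterochromatin calling between sexes and
    ages, repeat-family enrichment and Y-chromosome enrichment
    classification, copy-number-aware repeat expression analysis, and
    Kaplan-Meier survivorship estimation. Includes a synthetic-data
    generator that emulates a male/female Drosophila karyotype with a
    repeat-rich neo-Y chromosome and plants known effects (age-dependent
    pericentromeric heterochromatin loss, a neo-Y H3K9me3 deficit,
    male-biased transposable-element expression, Y-enriched repeat
    families, sex-specific lifespan), so every stage of the pipeline can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    survival,
    flexsurv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
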