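Package: lineatime
Title: Division-Timing Asynchrony Analysis for C. elegans Embryonic Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of cell division timing during C. elegans
    embryogenesis from 4D nuclei-tracking tables. Implements Sulston
    nomenclature logic and lineage-tree reconstruction, cycle-length
    extraction with censoring, the asynchrony-of-division-between-sisters
    (ADS) statistic, multi-embryo wild-type reference construction with
    D'Agostino K-squared normality assessment, RNAi-screen hit calling
    (50 percent ADS reduction, normal-tail significance, two-replicate rule),
    variance-buffering detection by F-test, embryo axis normalization,
    migration-deviation and Box-Cox division-angle statistics, and a seeded
    synthetic embryo-recording generator with the statistical structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    MASS,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
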