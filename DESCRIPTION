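Package: strainseed
Title: Strain Tracking in Family Gut Metagenomes with Rare Marker SNVs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking bacterial strain populations across fecal
    metagenomes of family members using rare marker single-nucleotide
    variants (rmSNVs). Implements pair-specific reference populations,
    rare/family/exclusive marker identification, marker-sharing similarity
    with strain-sharing calls, maternal-strain classification of infants,
    persistence and annual strain-replacement estimation, novel-SNV based
    transmission directionality within families, coverage-based species
    abundance and compositional similarity, beta-regression and linear-model
    group statistics, and a synthetic family-cohort simulator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
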