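Package: phenindex
Title: Phenological Index Scoring and Evaluation of Automated
    Reproductive-Organ Counts from Herbarium Specimens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the phenological status of herbarium
    specimens from counts of four classes of reproductive organs (buds,
    flowers, immature fruits, mature fruits) via the Phenological Index
    (PI), a proportion-weighted mean of class index values on the 1-4
    scale; for evaluating automated (e.g., instance-segmentation) organ
    detectors against manual counts through per-class counting errors,
    mean absolute error, concordance regressions, abundance-binned error
    distributions, and specimen-age effects; and for fitting PI-controlled
    phenological and phenoclimatic linear models of collection day-of-year,
    with per-term partial R-squared, confidence-interval model comparison,
    and derived quantities (days per century of flowering shift, days per
    PI unit of phenological progression).  Includes a seed-reproducible
    synthetic-collection generator emulating the count, climate, and
    phenology structure such analyses assume, a COCO-annotation count
    extractor, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
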