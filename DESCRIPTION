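Package: sporesalt
Title: Fungal-Spore Contributions to Sodium-Salt Aerosol in the Amazon
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale pipeline for quantifying fungal spores as a source of
    sodium-salt aerosol: rule-based single-particle classification from
    SEM/EDX elemental compositions and morphology, per-spore sodium mass
    estimation from carbon content and size, hygroscopic area and mass growth
    factors from hydration image pairs via segmentation and Beer-Lambert
    optical density, and apportionment of particulate sodium between
    sodium-rich fungal spores and sea salt on concentration time series with
    uncertainty bounds and threshold-exceedance statistics. A synthetic-data
    module generates particle tables, hydration image pairs, transmission
    maps, and concentration series with the statistical structure the
    analysis assumes, so every stage is exercisable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
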