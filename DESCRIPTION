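Package: proteoloc
Title: Quantitative Proteasome Localization Phenotyping in Starved Yeast
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify proteasome localization phenotypes in
    multi-channel fluorescence images of starved budding yeast. Provides a
    seeded synthetic-microscopy generator with per-cell ground truth,
    cell and nucleus segmentation, per-cell features (nuclear:cytoplasmic
    GFP ratio, proteasome storage granule punctum detection, Calcofluor
    White bud-scar counting), four-class phenotype and replicative-age
    calling, prevalence-by-age statistics with paired t-tests, CFW-extreme
    gating, and robust z-score hit calling for multi-round knockout
    screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
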