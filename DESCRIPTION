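Package: mobipot
Title: Mobilization Potential of Microbial Communities from Filter-Mating Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the plasmid-mobilizing potential of mixed microbial
    communities from solid-surface filter-mating assays imaged by fluorescence
    stereomicroscopy. Provides a seeded synthetic two-channel field-image
    generator with exact ground truth, a microcolony detection pipeline
    (background subtraction, intensity equalization, elliptic region-of-interest
    masking, automatic segmentation of bright objects above an area cutoff),
    scaling of scanned-zone transconjugant counts to whole-filter transfer
    frequencies (transconjugants per recipient), and the derived
    mobilization-potential calculus: community permissiveness in intrastrain
    equivalents, retromobilization probability, maximal mobilization potential,
    and fold changes, with delta-method and bootstrap uncertainty. A stochastic
    mating simulator of conjugation, direct mobilization and two-step
    retromobilization validates the estimators by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
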