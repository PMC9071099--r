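Package: ddrscreen
Title: Image-Based Quantification and Dose-Response Analysis for DNA
    Damage Response Reporter Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-content imaging screens of
    fluorescent DNA-damage-response (p53 pathway) reporter cell lines
    grown as 2D monolayers or 3D spheroids. Provides nuclei and
    cytoplasm segmentation with compartment-specific GFP intensity
    measurement, propidium-iodide death classification, spheroid
    quantification from maximum-intensity z-stack projections,
    concentration-response normalisation, loess-based point-of-departure
    (PoD) estimation against a solvent-control band, absolute IC50
    extraction from viability curves, comparative-Ct relative expression,
    and hierarchical clustering of reporter response profiles. A
    synthetic-data module generates images and plate tables with known
    ground truth so every stage is testable without raw screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
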