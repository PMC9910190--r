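Package: burnsev
Title: Burned-Area Severity Mapping and Remote-Sensing Ecological Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps burned-area severity from pre- and post-fire multispectral
    imagery using the differenced Normalized Burn Ratio (dNBR) and a two-stage
    Otsu maximum between-class-variance decision tree that separates heavily
    burned, mildly burned and unburned land, with area bookkeeping in hectares
    and accuracy/kappa assessment against reference maps. Also builds the
    Remote Sensing Ecological Index (RSEI) by principal-component fusion of
    greenness (NDVI), wetness (tasseled-cap), heat (single-channel land
    surface temperature) and dryness (bare-soil index) indicators, classifies
    it into five ecological levels, and quantifies pre/post-fire change with
    difference maps and level-transfer matrices. Includes a synthetic-scene
    generator with planted ground truth so the full pipeline is testable
    without satellite downloads, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
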