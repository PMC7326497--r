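Package: guvkin
Title: Quantification of Lipid-Kinase Activity on Giant Unilamellar Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying PI 3-kinase activity on giant unilamellar
    vesicles (GUVs) from two-channel confocal time-lapses. Segments GUV membrane
    rings with a difference-of-Gaussians filter followed by an internal
    morphological gradient of calibrated thickness, extracts per-vesicle
    intensity traces, subtracts a temporal background haze estimated from
    vesicle-free regions, locates the linear phase of the reporter recruitment
    curve and reports enzyme initial rates, fold changes between conditions and
    membrane curvature versus activity regressions. Includes a seeded forward
    model that renders synthetic GUV movies with known kinetics for validation,
    and a utility implementing standard hydrogen/deuterium-exchange
    mass-spectrometry peptide inclusion criteria, sequence coverage and uptake
    differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    IRanges,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
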