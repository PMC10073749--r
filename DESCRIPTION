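Package: nirfcorr
Title: Blood-Attenuation Correction for Intravascular NIRF-IVUS Imaging
Version: 0.1.0
Authors@R:
    person("NIRF-IVUS", "Maintainers", email = "maintainers@nirfcorr.dev",
           role = c("aut", "cre"))
Description: Quantitative correction of blood attenuation in hybrid
    near-infrared fluorescence (NIRF) and intravascular ultrasound (IVUS)
    pullback imaging using a fluorophore-coated guidewire as an in-situ
    reference. Implements the water-phantom calibration of the one-term
    exponential attenuation model, frame-by-frame estimation of the blood
    attenuation coefficient from the guidewire reference, two-media
    (in-sheath water plus intraluminal blood) signal correction, conversion
    of corrected intensities to fluorophore concentrations, accuracy and
    sensitivity evaluation, and a seeded phantom/artery pullback simulator
    used as the test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
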