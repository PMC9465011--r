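Package: bruisebands
Title: Waveband Selection and Spectral-Resolution Optimization for
    Multispectral Apple-Bruise Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing a rapid multispectral line-scan imager for
    detecting bruises on apples from visible/near-infrared hyperspectral
    reflectance data. Synthesizes hyperspectral apple scenes with realistic
    absorption features, pushbroom acquisition noise and a 14-bit EMCCD
    response model; performs flat-field calibration; selects key wavebands
    by principal-component pre-selection followed by sequential forward
    selection with four classifiers under cross-validation; models the
    exposure-time/spectral-ROI/dynamic-range trade-off of partial sensor
    readout to enumerate and rank spectral-binning combinations; and
    renders morphologically cleaned per-pixel and per-apple bruise
    classification maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    e1071,
    jsonlite,
    png,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
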