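Package: csdwave
Title: Widefield Imaging and EEG Analysis of Cortical Spreading Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cortical spreading depression (CSD) recorded with
    multispectral widefield optical imaging and cortical EEG. Implements the image
    conditioning chain for interleaved reflectance/fluorescence stacks (binning, detrending,
    resampling, brain masking, affine atlas registration, mean normalization), spectroscopic
    inversion of reflectance changes to oxy-/deoxyhemoglobin via the modified Beer-Lambert
    law, ratiometric hemodynamic correction of GCaMP fluorescence, wavefront speed estimation
    from position-time plots with ridge regression, inter-electrode EEG speed from
    cross-correlation lag, detection of low-voltage-activity (LVA) power-suppression events,
    paralysis scoring from behavior tracks, and EEG-behavior contingency statistics. A
    synthetic-scene generator produces widefield stacks, EEG traces, and behavior tracks with
    known ground truth so every stage is verifiable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
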