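Package: eggspeckle
Title: Eggshell Speckling Quantification and Cross-Fostering Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies protoporphyrin speckling on passerine eggshells from
    calibrated multispectral photographs: images are mapped to an avian
    double-cone (luminance) photon-catch channel, decomposed into seven
    spatial-frequency octave bands by Fourier filtering to obtain granularity
    spectra, and summarised as four pattern variables (marking size, pattern
    contrast, pattern coverage, pattern dispersion) that are aggregated to
    clutch level and reduced to principal-component speckling scores. Includes
    a synthetic-data module that renders speckled egg images with known ground
    truth and simulates complete double cross-fostering experiments, and an
    inference module fitting the associated provisioning general linear models
    and chick-mass mixed models with an origin-nest-within-foster-nest random
    intercept (REML, Satterthwaite degrees of freedom).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    EBImage,
    pracma,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
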