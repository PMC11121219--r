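Package: nirmeat
Title: NIR Chemometrics for Meat Quality Quantification and Breed
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chemometric workflow for near-infrared (NIR) spectroscopy of
    meat: spectral pre-treatments (Savitzky-Golay smoothing and
    derivatives, unit-area normalization, standard normal variate,
    multiplicative scatter correction, asymmetric least squares baseline
    removal), variable decimation, replicate-aware Kennard-Stone
    calibration/prediction partitioning, linear support vector regression
    and classification with RMSE/R2/slope model-selection criteria, and
    closed-form meat and lipid quality indices (carcass yield, CIELab
    chroma and hue, atherogenicity and thrombogenicity indices, the
    hypocholesterolemic/hypercholesterolemic ratio and fatty-acid family
    sums and ratios). Includes a synthetic two-breed goat-meat data
    generator so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
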