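Package: angiofish
Title: Label-Free Video-Subtraction Angiography and Gated
    Concentration-Response Analysis for Zebrafish Embryo Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the perfused tail vasculature of zebrafish
    embryos from brightfield video by frame subtraction (mean-frame
    difference, Gaussian blur, fixed-threshold binarization and
    accumulation), segments and counts intersegmental vessels (ISVs),
    and analyses per-embryo endpoints with a gated concentration-response
    pipeline (dichotomization against pooled controls, Tukey-type trend
    test over dose metameters, AIC model selection, effect-magnitude
    gate, log-logistic EC10/EC50 estimation).  Includes a baseline
    toxicity QSAR and sensitivity-ratio classification of specific
    anti-angiogenic activity, plus a fully parameterised synthetic
    generator of ground-truthed flow videos and dose-response datasets
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    png,
    jsonlite,
    multcomp,
    sandwich,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
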