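Package: cttasurv
Title: Filtration-Histogram CT Texture Analysis and Prognostic Stratification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Filtration-histogram texture analysis of masked CT lesions:
    Laplacian-of-Gaussian band-pass filtering at named spatial scales followed
    by bias-corrected excess kurtosis of the in-mask attenuation histogram,
    with automatic gas exclusion below -50 HU. Per-patient aggregation of
    multi-lesion measurements (up to five most FDG-avid lesions, averaged),
    marker screening by Mann-Whitney tests, and progression-free-survival
    stratification via optimal-cutpoint Kaplan-Meier analysis with
    Benjamini-Hochberg false-discovery-rate control, Cox proportional-hazards
    modelling with a texture-by-interim-PET interaction, and three-tier risk
    grouping. Ships phantom and cohort simulators so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    survival,
    RNifti,
    png,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
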