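Package: miraf
Title: Simulation and Segmentation for Multimodal Mid-Infrared and
    Autofluorescence Tissue Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-based simulator and analysis chain for multimodal
    label-free tissue imaging that combines a four-laser flying-spot
    mid-infrared (MIR) scanner with autofluorescence camera imaging.
    Generates synthetic brain-tissue phantoms with known ground truth,
    simulates Beer-Lambert absorbance with a scattering baseline, Gaussian
    flying-spot rastering, an FTIR-like dense-band reference modality, and
    an LED x emission-filter autofluorescence camera path; implements the
    processing chain (count normalization, gold-reference absorbance
    conversion, dual-reference scattering correction, bicubic upscaling,
    phase-correlation registration, datacube assembly), K-means tissue
    segmentation with k-means++ initialization and Davies-Bouldin guided
    model selection, and quantitative evaluation via contingency tables,
    the adjusted Rand index, and line-grating contrast/resolution analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
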