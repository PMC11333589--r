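Package: tdbreast
Title: Time-Domain Diffuse Optical Spectroscopy of Breast Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for broadband (600-1100 nm) time-domain diffuse
    optical spectroscopy (TD-DOS) of breast tissue. Implements time-resolved
    diffusion-equation forward models for semi-infinite (reflectance) and slab
    (transmittance) geometries with extrapolated boundary conditions,
    instrument-response-function convolution, single-wavelength and
    spectrally-constrained curve fitting that retrieves water, lipid, collagen,
    oxy- and deoxy-hemoglobin concentrations and Mie scattering parameters,
    breast-density optical indices (OI, CI), a protocol-faithful synthetic
    cohort generator with Poisson counting noise, and the configuration
    comparison statistics (Pearson correlations, exact Wilcoxon signed-rank
    tests, Bonferroni adjustment, density rankings) used to compare measurement
    geometries, postures, probing positions and source-detector distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
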