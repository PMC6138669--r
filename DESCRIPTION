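Package: hsei
Title: Hyperspectral Endoscopic Imaging from RGB Endoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a reflectance spectrum for every pixel of an RGB
    endoscopic image by colour-checker calibration and a principal-component
    spectral basis, automatically extracts intraepithelial papillary
    capillary loop (IPCL) pixel coordinates from narrow-band-imaging frames
    with a thinning-based segmentation pipeline, and assigns oesophageal
    neoplasia stages with a triangle-region classifier in principal-component
    score space. Includes a synthetic-fixture generator (colour checkers,
    camera model, tissue spectra, vessel scenes) so the full pipeline can be
    exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    grDevices,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
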