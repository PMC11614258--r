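Package: avicube
Title: Hyperspectral Imaging Pipeline for Animal Coloration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for analysing hyperspectral images of
    animal coloration. Reads and writes ENVI data-cubes, converts radiance
    to reflectance with a bright-image flat-field and an in-scene white
    standard, lays uniform sampling grids over plumage patches and extracts
    windowed-median reflectance spectra, preprocesses spectra (1 nm
    interpolation, Savitzky-Golay smoothing, monotone-cubic ultraviolet
    extrapolation), embeds spectra in a visual-system-independent space
    (per-patch PCA followed by UMAP, with highest-density-region contours
    and density-mode spectra), models avian tetrachromatic vision (quantum
    catches, tetrahedral colour coordinates, receptor-noise-limited
    chromatic and luminance contrasts), registers images to 3D meshes via
    landmarks to derive per-pixel surface-normal pitch and roll, and
    simulates fully ground-truthed synthetic scenes for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    png,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    uwot
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
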