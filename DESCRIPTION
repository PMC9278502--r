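Package: imgtsne
Title: Image t-SNE Galleries for Multiplexed Tissue Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gallery views of multiplexed tissue-imaging cohorts
    (Vectra, CyCIF, t-CyCIF, CODEX). Reads multichannel images from plain
    multi-page TIFF, OME-TIFF and pyramidal QPTIFF containers, denoises and
    composites user-selected marker channels (median filter, Otsu
    thresholding, morphological closing, border clearing, foreground
    upweighting), downscales them to thumbnails with optional
    metadata-colored borders, and places the thumbnails on a static PNG
    canvas by user-supplied embedding coordinates, a vertical grid, or
    Poisson-disc random positions. A matching interactive scatterplot with
    per-image hover metadata is written as a standalone HTML document. When
    no coordinates or labels are supplied, an inbuilt fallback abstracts
    each image to its first six channel means, embeds the cohort with exact
    t-SNE and clusters it with a variational Bayesian Gaussian mixture. A
    stack-montage mode renders every channel of a single image as a
    labelled grid. A synthetic-cohort generator fabricates realistic
    multichannel fixtures so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
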