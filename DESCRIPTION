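Package: mfractal
Title: Multiscale Fractal Analysis and Classification of Grayscale Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the generalized Hurst exponent spectrum H(q) of
    one-dimensional signals by the structure-function (multiscale analysis)
    method, converts grayscale images to signals by row concatenation,
    and classifies the resulting six-component fractal feature vectors
    with a soft-margin support vector machine using an inhomogeneous
    polynomial kernel, evaluated by leave-one-out cross-validation.
    Includes synthetic generators (fractional Brownian motion via exact
    circulant embedding, random walks, two-class spectral-synthesis
    fractal textures) so the full pipeline can be exercised and validated
    without external image data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
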