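Package: relcolors
Title: Relevant Colour Palettes and Spatio-Chromatic Statistics of Paintings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the small set of 'relevant colours' that describe the
    colour palette of a painting and the colourimetric statistics around them.
    Provides CIELAB colour handling (sRGB conversion, chroma/hue polar form,
    an RG/BY opponent plane), per-image gamut descriptors (discernible-colour
    counts on unit cells, convex-hull colour volume, direct least-squares
    gamut ellipse), density-ranked relevant-colour extraction with lightness
    and chroma gates, aggregation of observer colour selections, nearest-colour
    palette segmentation with per-channel correlation fidelity, PHOG-based
    image complexity metrics (self-similarity, complexity, anisotropy, a
    Birkhoff-like ratio), and an independent component analysis of image
    patches yielding preferred colour directions in the opponent plane.
    Includes synthetic-painting and synthetic-observer generators so the whole
    pipeline is testable without external image datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    tools,
    utils,
    ica,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    farver,
    jpeg,
    withr
Config/testthat/edition: 3
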