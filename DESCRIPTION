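Package: knottrack
Title: Tracking Self-Intersecting Filaments in Microscopy Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments and tracks single, highly curved, self-intersecting
    filaments (for example clamped microtubules in motor gliding assays)
    in fluorescence microscopy time series. Knotted one-pixel skeletons
    are mapped to directed graphs of branch and segment vertices;
    cross-overs are resolved by capped path enumeration and dynamic time
    warping against the previously resolved contour. Includes a synthetic
    image-formation and noise model for oscillating clamped filaments,
    contour geometry analysis (tangent angle, curvature, end-to-end
    distance, power spectra), and tolerance-based Dice and discrete
    Frechet accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    Rcpp,
    signal,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
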