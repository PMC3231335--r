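Package: phenocrown
Title: Detection of Mass-Flowering Tree Crowns in High-Resolution
    Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@phenocrown.org",
           role = c("aut", "cre"))
Description: Detects individually flowering tree crowns in high-resolution
    (Quickbird-like, 4-band) multispectral reflectance imagery and tracks
    them across acquisition dates. A one-class support vector machine with
    an RBF kernel extracts pure flower pixels, whose average defines the
    target endmember; per-pixel spectral angle mapping and fully
    constrained linear spectral unmixing are fused by an explicit
    fraction/angle threshold rule; ISODATA clustering isolates flower
    objects which are reduced to crown centroids and consolidated by a
    buffer merge; bi-temporal centroid matching partitions crowns into
    common, lost and newly flowering trees. Includes a synthetic scene
    generator with known crown ground truth so the full pipeline is
    testable without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    e1071,
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
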