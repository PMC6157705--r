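Package: scatterseg
Title: Model-Free Classification and Segmentation of Scanning SAXS/WAXS Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies azimuthally integrated scattering curves I(q) from
    scanning small- and wide-angle X-ray scattering (SAXS/WAXS) experiments
    without structural models. Curves are normalized by their mean intensity,
    logarithmically rebinned, and reduced to a sparse feature matrix of
    intensities at inflection points (zeros of the first or second derivative).
    Principal component analysis with an L-curve diagnostic reduces the
    features, k-means with the silhouette criterion selects the number of
    clusters, and scan maps are segmented accordingly. Representative signals
    per cluster are extracted either as the member nearest the centroid or as
    the mean of the members furthest from all centroids, and per-pixel Pearson
    correlation maps against each representative are thresholded at the map
    median and composed into RGB images. A synthetic phantom generator with
    known phase composition (Gaussian Bragg lines on power-law plus constant
    backgrounds, Poisson counting noise) makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
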