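Package: tsmapper
Title: Mapper Shape Graphs for Temporal Neuroimaging Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A deconstructed Mapper pipeline for time-by-feature matrices
    such as fMRI parcel time series. Provides the five pluggable stages of
    the algorithm (pairwise distances including a penalized reciprocal
    k-nearest-neighbor geodesic metric, extrinsic embedding lenses with a
    delegation registry plus the intrinsic k-NN-graph lens, overlapping
    rectangle or farthest-point-sampling landmark covers, partial
    clustering by single linkage or density, and shape-graph assembly),
    validation criteria (coverage, autocorrelation, entropy) and
    goodness-of-fit procedures (circleness of simulated state trajectories;
    changepoint-based transition extraction with average-delay scoring),
    synthetic generators (trefoil knot, coupled two-population network
    simulator, circular-trajectory generator, SNR-controlled noise,
    smoothed downsampling, block-shuffled nulls), and a JSON-configured
    grid runner for cohort batch exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    parallel
Suggests:
    vegan,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
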