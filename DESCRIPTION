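Package: somtopo
Title: Topographic Mapping of High-Dimensional Feature Spaces with
    Self-Organizing Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains two-dimensional Kohonen self-organizing maps over
    high-dimensional nonnegative feature embeddings (such as the penultimate
    layer of a convolutional network), using principal-plane initialization,
    eigenvalue-ratio grid shaping, and linearly decaying learning-rate and
    neighborhood schedules. From a trained map it derives spatial activation
    maps, condition preference maps, and category-selectivity maps (d-prime
    and selectivity index), and quantifies the spatial nesting of mesoscale
    selectivity within macroscale preference zones via an ROC threshold sweep
    with a permutation null. Includes representational-geometry summaries
    (correlation-distance dissimilarity matrices and multidimensional
    scaling), a seeded synthetic "object space" generator with planted
    animacy and real-world-size axes for end-to-end testing, delimited and
    binary serialization of all artifacts, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
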