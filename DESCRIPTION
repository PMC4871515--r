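Package: mstmc
Title: Multiscale Spatio-Temporal Statistical Model Checking for Timed
    Simulation Traces
Version: 0.1.0
Authors@R:
    person("Model", "Checking Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates probabilistic bounded linear multiscale spatial
    temporal logic specifications against timed simulation traces of
    multilevel biological models. Provides a rooted-tree multiscale
    architecture graph with partial orders over (scale, subsystem)
    vertices, an XML trace format for numeric state variables and
    detected spatial entities, automatic detection of emergent regions
    (Moore-connected thresholded components) and clusters (DBSCAN over
    region centroids) in discretised spatial data together with eleven
    spatial measures, a parser and sample-based evaluator for the
    bounded spatio-temporal logic, and five approximate probabilistic
    model-checking algorithms (probabilistic black-box,
    Chernoff-Hoeffding bound estimation, Wald's sequential probability
    ratio test, Bayesian mean/variance estimation and Bayesian
    hypothesis testing with Bayes factors). Includes a fixture module
    that generates a fully enumerable toy multiscale model with exact
    transition probabilities, synthetic grids with known spatial ground
    truth and Bernoulli outcome streams, plus a command-line entry
    point tying analysis, specification and checking together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
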