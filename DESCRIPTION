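Package: cascademc
Title: Stochastic Modeling of Stationary Biological Cascades by Bootstrapped
    Sigmoid Regression and Monte Carlo Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven stochastic modeling of multiscale stationary
    biological cascades such as quantitative adverse outcome pathways.
    Fits Hill-type sigmoid dose-response curves to paired response-response
    data for each edge of a single-parent cascade network, quantifies
    coefficient uncertainty by residual bootstrapping, and propagates an
    input activity through the network by Monte Carlo sampling of edge
    parameters from the Gaussian distributions underlying the bootstrap
    confidence intervals. Provides conditional probability-density clouds
    of node responses, and detects lower and upper input-activity
    thresholds that partition the response into regions of no, weak, and
    strong impact using sequential two-sample Kolmogorov-Smirnov tests.
    Includes a synthetic-cascade generator with known ground truth for
    validation, and a command-line interface for the end-to-end workflow.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
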