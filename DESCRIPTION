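Package: statefda
Title: Latent-State Functional Data Analysis for Curve-Valued Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nested functional data analysis for time series of curves, such as
    sequences of EEG power spectral densities. Fits a functional hidden Markov
    model with distance-based emissions over curve-valued observations,
    decodes latent state sequences with the Viterbi algorithm, stabilises
    centroid initialisation by consensus over subsampled model fits, computes
    per-individual state-occupancy dynamics, and performs functional principal
    component analysis within each latent state using penalised B-spline
    bases. Includes a spectral parameteriser separating aperiodic 1/f
    background from Gaussian oscillatory peaks, a synthetic-data generator
    with known ground truth, CSV/JSON input-output, and an end-to-end
    pipeline driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    splines,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
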