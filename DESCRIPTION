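Package: edarousal
Title: Sympathetic Arousal Decoding from Skin Conductance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes sympathetic arousal from single-channel skin conductance
    (electrodermal activity) recordings in two stages. First, the phasic signal
    is deconvolved into a sparse train of sudomotor neural impulses while the
    subject-specific rise and decay time constants of the skin conductance
    response are estimated by a two-step coordinate descent combining
    iteratively reweighted least squares sparse recovery (FOCUSS+ with
    generalized cross-validation for the regularization weight) and
    box-constrained nonlinear system identification. Second, a state-space
    model with a latent random-walk arousal state and Bernoulli-distributed
    impulse occurrences is fitted by Expectation-Maximization with an
    approximate Gaussian forward filter and fixed-interval smoother, yielding
    smoothed arousal trajectories and a High Arousal Index. Includes a convex
    tonic/phasic decomposition, a ground-truthed synthetic-data generator, and
    a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    pracma,
    Rcpp,
    splines,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
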