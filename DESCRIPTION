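Package: effparam
Title: Data-Driven Effective Parameters and Nonidentifiability Analysis for Kinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize parameter (non)identifiability of dynamical
    models observed only through input-parameter to output-time-series pairs.
    Given an ensemble of parameter vectors and the behaviors they produce, the
    package counts the effective parameter combinations (the intrinsic dimension
    of the model manifold) with output-informed diffusion maps and parsimonious
    eigenvector selection, builds invertible maps between data-driven
    coordinates, candidate physical effective parameters and behaviors via
    geometric harmonics (the Double DMaps construction) and small neural
    networks, disentangles behavior-driving from redundant parameter
    combinations with a conformal autoencoder trained under a gradient
    orthogonality penalty, extracts effective parameters as jointly smooth
    functions over parameter and output datasets, and traces explicit level
    sets of constant behavior in full parameter space. Ships mass-action
    kinetic testbeds (a dual-phosphorylation mechanism, its quasi-steady-state
    reduction, and a single-site caricature) so every analysis can be exercised
    end to end on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
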