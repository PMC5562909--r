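Package: pemnet
Title: Meta-Stable Pattern Networks and Ensemble-Model Property Prediction
    for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines excited-state molecular dynamics trajectories for
    meta-stable conformational patterns by K-means clustering of
    dihedral-angle descriptors, builds the kinetic transition network
    among patterns (transition counts, row-stochastic probabilities,
    graph components and articulation vertices, time-dependent pattern
    populations), characterizes per-pattern property distributions with
    Gaussian fits and coverage intervals, and predicts molecular
    properties (excitation energies, per-atom partial charges) for
    arbitrary conformers with the Prediction-with-Ensemble-Models (PEM)
    Shepard-type kernel interpolation over per-pattern reference
    conformers. Includes a synthetic-trajectory generator (Markov chain
    over latent conformational states with von Mises dihedral emissions
    and smooth Fourier property surfaces) so the whole pipeline is
    testable without electronic-structure data, plus multi-frame XYZ and
    delimited property-table IO and an end-to-end pipeline runner.
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
    graphics,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    mclust,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
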