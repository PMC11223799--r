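Package: rnacg
Title: Coarse-Grained RNA Folding Simulations with Restraints and Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-grained (five beads per nucleotide) RNA 3D folding
    simulator and trajectory-analysis toolkit. Provides Metropolis Monte
    Carlo sampling with simulated annealing and replica exchange, hard
    (slope-penalty) and soft (well-bonus) restraints on canonical and
    noncanonical base pairs in Leontis-Westhof notation, Watson-Crick-edge
    exclusion marks, chemical-probing (SHAPE/DMS) reactivity restraints,
    frozen-residue simulations, and post-simulation analysis: best-fraction
    frame selection, all-against-all RMSD matrices with or without
    superposition, three clustering strategies with representative
    extraction, and base-pair Matthews correlation coefficient evaluation.
    Includes generators for idealized helices, hairpins, alternative-register
    and quadruplex-like fixtures so every analysis can run from synthetic
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
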