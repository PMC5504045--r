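Package: patchyfold
Title: Design and Folding of Patchy Heteropolymers by Monte Carlo
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for coarse-grained patchy
    heteropolymers: chains of hard beads carrying an alphabet of isotropic
    pair interactions plus directional surface patches. Implements the
    freely-rotating (FRC) and freely-jointed (FJC) chain models, Metropolis
    Monte Carlo in conformation and sequence space with replica exchange
    over a temperature ladder, and the three-stage SEEK-DESIGN-FOLD
    protocol that classifies a polymer architecture (patch number times
    alphabet size) as designable or not. Analysis tools include DRMSD and
    superposition RMSD order parameters, radial distribution functions
    with ideal-gas normalisation, peak-area designability fingerprints,
    free-energy profiles with convergence checks, and C-alpha g(r)
    profiles of protein structures for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
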