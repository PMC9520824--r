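Package: annealbind
Title: Grid-Based Simulated Annealing Prediction of Multivalent Ligand
    Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts binding sites of large, flexible, multivalent charged
    ligands on protein surfaces. A five-bead bead-spring ligand (harmonic
    springs, hard-sphere excluded volume) interacts with the protein through
    precomputed per-fragment affinity grids; an ensemble of simulated-annealing
    Metropolis Monte Carlo searches locates low-energy poses, which are then
    clustered (k-medoids) and scored for two-fold rotational symmetry.
    Includes readers and writers for PQR structures and OpenDX scalar grids,
    a screened-Coulomb (Debye-Hueckel) potential generator, a rotational
    rigid-probe scanner for building affinity maps, and synthetic
    planted-minimum instances with an exact brute-force oracle for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    graphics,
    utils,
    cluster,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
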