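Package: boostmd
Title: Dual-Boost Accelerated Molecular Dynamics on Desk-Scale Model Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Langevin molecular dynamics with an optional dual-boost
    accelerated-MD (aMD) bias potential, threshold parameterization from a
    short unbiased pre-run, and Boltzmann reweighting of boosted trajectories
    back to the canonical free-energy landscape over (RMSD, radius of
    gyration). Ships desk-scale model systems with analytic gradients -- a
    one-dimensional double well, a harmonic oscillator, and a coarse-grained
    Go-like helical peptide -- together with the folding analytics used to
    judge convergence: Kabsch-superposition RMSD, fractional native contacts,
    radius of gyration, helix content, and average-linkage trajectory
    clustering. Trajectories persist as multi-model PDB plus per-frame scalar
    CSV; a command-line driver chains the stages.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
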