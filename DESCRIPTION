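Package: photoppi
Title: Kinetic, Spectroscopic and Trajectory Analysis of Light-Switchable
    Protein-Protein Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing photoswitchable protein-protein
    interactions such as those between cyanobacteriochrome (CBCR) GAF
    domains and state-selective binders. Implements inference of
    state-specific dissociation constants from binder-modulated thermal
    reversion kinetics, 1:1 equilibrium titration fitting with receptor
    depletion, a formula-defined NMR chemical-shift-perturbation residue
    classifier that exports docking restraints, and molecular-dynamics
    trajectory post-processing (RMSD stability windows, medoid frame
    selection, hydrogen-bond occupancy). A synthetic-data module emulates
    every experimental input with recorded ground truth so the whole
    pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    deSolve,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
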