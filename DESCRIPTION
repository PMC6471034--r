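Package: quadbind
Title: Binding Modes, Order Parameters and MM-GBSA Energetics for
    Ligand-DNA Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory analysis for small-molecule binding to G-quadruplex
    and duplex DNA: stable-complex detection by atom contacts, Daura RMSD
    clustering of ligand poses into binding-mode families, classification of
    poses into end-stacking (top/bottom) and groove modes, binding-pathway
    order parameters (tetrad hydrogen bonds, drug-tetrad plane angle,
    receptor/ligand RMSD, center-to-center and channel ion distances,
    backbone torsions and base-flip detection), and a from-scratch MM-GBSA
    engine (Lennard-Jones, Coulomb, Hawkins-Cramer-Truhlar generalized Born
    with Debye-Hueckel salt screening, Shrake-Rupley surface area) with a
    three-trajectory decomposition and delta-delta-G ranking of binding
    modes.  Includes an idealized structure generator (three-tetrad
    quadruplex, B-form duplex, planar tricyclic ligand) and a scripted
    trajectory generator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
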