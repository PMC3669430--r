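Package: mmcg
Title: Hybrid Molecular Mechanics/Coarse-Grained Molecular Dynamics for
    Receptor-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid multiscale molecular-dynamics engine and trajectory
    toolkit for membrane receptor-ligand complexes. The binding cavity,
    ligand and a surrounding water droplet are treated atomistically
    (harmonic bonded terms, Lennard-Jones and Coulomb nonbonded terms,
    rigid SPC water) while the remaining protein frame is coarse-grained
    with a structure-based (Go-like) C-alpha potential; an interface
    region couples the two resolutions. The membrane is implicit:
    half-harmonic confining walls (planar slab, hemispheric caps, a
    lateral wall following the initial protein surface) plus a spherical
    droplet wall. Dynamics are stochastic (Langevin, BAOAB splitting)
    with SHAKE/RATTLE constraints on hydrogen-containing bonds and rigid
    water. The analysis layer provides Kabsch superposition, C-alpha RMSD
    time series, ligand-pose clustering with the greedy largest-
    neighborhood algorithm, hydrogen-bond geometry series and labeled
    distance tables. A fixtures module generates fully synthetic helical-
    bundle receptors, ligands and water droplets so the whole pipeline is
    testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    tibble,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
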