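Package: tcrdyn
Title: Post-Simulation Analysis of pMHC-TCR Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for the comparative analysis of
    molecular-dynamics ensembles of peptide-MHC-T-cell-receptor complexes:
    least-squares superposition, RMSD/RMSF fluctuation profiles, essential
    dynamics with combined-trajectory common subspaces and 2D projections,
    thresholded dynamic cross-correlation maps, residue-contact network
    metrics (degree, closeness centrality), hydrogen-bond occupancy and
    peptide anchor-site analysis, rotation-invariant 3D Zernike descriptors
    of binding-groove shape and electrostatics, grid-based lipid-bilayer
    thickness maps, and region-pair nonbonded interaction-energy
    distributions. Ships a synthetic-data generator that plants known
    covariance structure, hydrogen-bond occupancies, bilayer geometry and
    charge distributions so that every analysis stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
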