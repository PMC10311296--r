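Package: voxddg
Title: Local Voxel Models of Protein-Protein Interfaces and Binding
    Affinity Changes upon Mutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deconstructs protein-protein interfaces into locally oriented,
    residue-centered voxel cubes and learns from them with 3D convolutional
    networks. Provides PDB structure handling with a 167-channel
    (residue, heavy-atom) one-hot encoding, solvent-accessibility based
    classification of interface residues into support/core/rim layers,
    Gaussian-density voxelization in a backbone local frame with spherical
    masking for self-supervised masked-residue recovery, a Siamese network
    predicting binding free-energy changes (ddG) of point mutations from
    wild-type and mutant cubes plus structural and evolutionary auxiliary
    features, a SKEMPI-style mutation table harness with mutation- and
    complex-based splits and PCC/RMSE evaluation, and deterministic
    synthetic-fixture generators so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
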