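Package: eqbind
Title: Equivariant Graph Neural Network Scoring of Protein-Ligand Binding Affinity
Version: 0.1.0
Authors@R:
    person("eqbind", "maintainers", email = "eqbind@example.org", role = c("aut", "cre"))
Description: An end-point scoring function for protein-ligand binding affinity
    (pKi) built on an E(3)-equivariant message-passing neural network. A complex
    is represented as two disconnected spatial graphs (protein and ligand) with
    distance cutoffs; interatomic distances are expanded on a Bessel radial basis
    with a smooth polynomial envelope. The predicted pKi is a trainable shift plus
    a sum of per-ligand-atom contributions and per ligand-protein atom-pair
    contributions, each produced by small dense networks over rotation-invariant
    features. The package includes readers and writers for PDB/SDF/MOL2, binding
    pocket extraction, direct training with online coordinate augmentation,
    stratified splitting, k-fold ensembling, transfer learning onto congeneric
    ligand series, a synthetic affinity oracle for desk-scale benchmarking, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
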