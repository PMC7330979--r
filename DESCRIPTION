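Package: triadmut
Title: Propose Stabilizing Mutation Pairs from Backbone-Conserved
    Interaction Templates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Proposes pairs of simultaneous point mutations that introduce
    a new side-chain interaction (hydrogen bond, ionic pair or disulfide
    bond) into a target protein structure.  Templates are triad pairs (two
    interacting residues plus their sequence flanks) mined from known
    structures, clustered by single linkage on main-chain RMSD, and
    matched to candidate site pairs by Kabsch superposition of the 24
    main-chain atoms, with a cutoff-scanning fingerprint and SVD-based
    Euclidean pre-filter, steric clash screening of grafted side chains,
    and contact-count evaluation of the resulting mutants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
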