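Package: miniscreen
Title: Graph Transformer Networks for Minisci C-H Alkylation Yield
    Prediction and In Silico Reaction Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts reaction yield and binary reaction outcome for
    Minisci-type late-stage C-H alkylation of N-heteroarenes with alkyl
    carboxylic acids. Implements a dual-graph transformer neural network
    operating on 3D (or 2D) molecular graphs of the two reactants together
    with a learned reaction-condition representation, trained by
    reverse-mode automatic differentiation. Includes reading, validation
    and writing of tab-separated SURF (Simple User-friendly Reaction
    Format) reaction tables, decoy-reaction generation from non-aromatic
    substrates, ensemble in silico screening of building-block libraries
    with uncertainty estimates, ECFP4/Jaccard fingerprint clustering
    (agglomerative and sphere exclusion), diversity-aware substrate
    selection, evaluation metrics (MAE, Pearson r, four-bin yield
    confusion, binary accuracy and F-score), and a seeded synthetic-data
    generator with planted substrate- and acid-class yield effects for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (obabel on the PATH) for SMILES
    standardization and fingerprints; Python with RDKit (python on the
    PATH) for seeded 3D conformer embedding
Config/testthat/edition: 3
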