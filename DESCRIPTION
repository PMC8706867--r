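Package: molgru
Title: GRU-Based SMILES Language Modelling, Transfer Learning and
    Ligand-Based Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A combinational de novo molecular design toolkit. Trains a
    gated recurrent unit (GRU) language model on SMILES strings, biases
    it towards a small focused inhibitor set by transfer learning, and
    screens the sampled molecules with descriptor-based binary
    classifiers, a t-SNE chemical-space embedding over seven physico-
    chemical properties, and per-residue contact-frequency analysis of
    docked protein-ligand poses. Includes a strict SMILES parser and
    validity checker, a corpus curation pipeline, and seeded synthetic
    data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    e1071,
    class,
    randomForest,
    glmnet,
    pROC,
    bio3d,
    ChemmineOB
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
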