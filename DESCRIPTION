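Package: csom
Title: Consensus Self-Organizing Maps for Imbalanced Multi-Class Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains two-dimensional toroidal self-organizing maps and turns them
    into multi-class classifiers by a probability-expansion algorithm: class
    distributions of mapped training examples are propagated wavefront-wise
    across the torus until every map cell carries a class-probability vector.
    Per-example prior distributions are estimated by consensus over repeated,
    independently seeded map trainings, and predictions below a confidence
    threshold are reported explicitly as non-conclusive rather than forced into
    a class. Includes SMOTE oversampling and random undersampling for
    imbalanced data, imbalance-aware evaluation metrics (mean and geometric
    mean recall, macro F-measure, percent non-conclusive), stratified k-fold
    cross-validation with k-nearest-neighbour baselines in feature and map
    space, descriptor preparation operators (correlation pruning, sigmoid
    scaling, SVD-based linear autoencoding), readers for delimited and KEEL
    tables, and a synthetic-data generator emulating strongly imbalanced
    Gaussian class structures. Motivated by the classification of ABC
    transporter (P-glycoprotein, MRP1, BCRP) substrates from molecular
    descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
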