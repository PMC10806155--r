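Package: senseFuse
Title: Mid-Level Data Fusion for Multi-Sensor Identification of Herbal
    Decoction Pieces
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mid-level (feature-level) data fusion for authenticating herbal
    decoction pieces from heterogeneous instrument blocks such as electronic
    nose, electronic tongue, electronic eye and HPLC fingerprints. Provides
    per-block z-score standardization with calibration-only statistics,
    leakage-free principal component score projection, NIPALS partial least
    squares latent-variable extraction with leave-one-out selection,
    Kennard-Stone sample partitioning, fusion of per-source component scores,
    three classification back-ends (PLS-DA with an unassigned-sample
    convention, RBF-kernel SVM with grid search, momentum back-propagation
    neural network), confusion accounting with separate misclassified and
    unassigned tallies, ROC/AUC, and contribution analysis via univariate
    Wilk's lambda and principal-component factor loadings. A synthetic
    multi-source generator emulating a four-class study design makes the whole
    pipeline runnable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'pls.R'
    'classifiers.R'
    'evaluate.R'
    'fuse.R'
    'pca.R'
    'interpret.R'
    'io.R'
    'synthetic.R'
    'standardize.R'
    'pipeline.R'
    'senseFuse-package.R'
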