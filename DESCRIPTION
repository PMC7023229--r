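Package: fdQSAR
Title: Kohonen Maps and Counter-Propagation Networks for Fullerene-Derivative
    Binding Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cheminformatics toolkit for analysing the protein-binding activity of
    fullerene derivatives from drug-like molecular descriptors. Implements a
    self-organizing Kohonen map engine (winner search, triangular neighborhood,
    linear learning schedules) and a counter-propagation artificial neural network
    (CPANN) regressor with leave-one-out cross-validation, together with the
    surrounding analysis pipeline: SOM-based reduction of protein binding profiles,
    SOM-based descriptor selection and consensus feature sets, binding-score
    averaging and deltas against pristine C60, activity-sector and saturation
    classification, Pearson correlation tables and PCA loading analysis, and a
    seeded synthetic-data generator with known latent structure for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
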