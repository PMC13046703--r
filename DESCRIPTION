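Package: tobtrace
Title: Geographical Origin Traceability of Tobacco Leaves from Chemical
    Composition Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric toolkit for discriminating the geographical
    origin of flue-cured tobacco leaves from a 70-component chemical
    composition table. Ships per-country component statistics as
    fixtures, generates synthetic composition tables with that marginal
    structure, screens regional differences with one-way ANOVA, Tukey
    HSD and compact letter displays, clusters mean regional profiles
    with Pearson-correlation distance, trains multiclass support vector
    machines on precomputed Gram matrices including a simplex-weighted
    hybrid kernel (linear + polynomial + Gaussian), tunes
    hyperparameters by particle swarm optimization with five-fold
    cross-validated accuracy as fitness, evaluates with macro-averaged
    recall, precision and F1, and ranks discriminating chemical markers
    by permutation feature importance under a 1 - AUC loss. Baseline
    backpropagation neural network and random forest classifiers are
    included for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    kernlab,
    randomForest,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
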