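Package: bcrpsvm
Title: Support Vector Machine Classification of BCRP (ABCG2) Substrates
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating support vector machine (SVM)
    classifiers that predict whether a small molecule is a substrate of the
    wild-type human breast cancer resistance protein (BCRP/ABCG2). Provides
    ingestion of SDF/SMILES structures and Dragon-style descriptor tables,
    native computation of five 3D molecular descriptors (mean information
    index on atomic composition, spherosity, two mass-weighted 3D-MoRSE
    signals, and a mass-weighted GETAWAY R autocorrelation), descriptor
    filtering and min-max scaling, F-score feature ranking with correlation
    pruning and greedy forward selection, kernelized SVM training with
    exponential grid search over cost and gamma, confusion-matrix metrics
    (accuracy, sensitivity, specificity, Matthews correlation coefficient),
    a multi-run random-split evaluation protocol with kernel and train/test
    ratio comparisons, gap-based model selection, cross-model classification
    overlap analysis, and a synthetic descriptor-data generator with planted
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    e1071,
    ChemmineR,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
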