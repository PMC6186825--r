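Package: ewrsvmc
Title: Evolutionary Weighted Random SVM Clusters for Functional-Connectivity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted ensembles of randomly subsampled radial-basis-function
    support vector machines for binary classification of resting-state functional
    connectivity, with an iterative weight-driven feature-elimination ("evolution")
    loop. Includes Pearson functional-connectivity feature extraction from ROI
    time series, weighted-vote prediction, confusion-matrix metrics, ranking of
    discriminative brain regions by endpoint frequency, and a synthetic-connectome
    generator with planted region-pair effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
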