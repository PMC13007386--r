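Package: rsafusion
Title: Model-Based MEG-fMRI Fusion of Decoding-Based Representational Dissimilarities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying where and when task information is encoded in
    the brain by fusing functional MRI and magnetoencephalography through
    representational similarity analysis. The package builds representational
    dissimilarity matrices from cross-validated linear-SVM decoding accuracies
    (leave-one-block-out for region-of-interest fMRI beta patterns,
    time-resolved 10-fold for MEG sensor epochs), constructs binary model
    dissimilarity matrices for distinct task features, and computes a
    three-way commonality index (raw Spearman correlation between the fMRI
    and MEG dissimilarity vectors minus their partial Spearman correlation
    given the model) at every MEG time point. Inference uses label-permutation
    null distributions with Storey's adaptive false-discovery-rate correction
    across time, plus Jeffreys-Zellner-Siow Bayes-factor t-tests for decoding.
    A synthetic-data generator emulates a four-position stimulus-response
    mapping paradigm with planted, window-limited multivariate effects so the
    full pipeline is testable end to end without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
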