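Package: cpmconn
Title: Connectome-Based Predictive Modelling of Behaviour from Functional
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Predict behavioural scores from whole-brain resting-state
    functional connectivity with connectome-based predictive modelling
    (CPM).  Provides connectome construction from ROI time series
    (Pearson correlation, Fisher z transform), phenotype-based subject
    filtering, empirical-Bayes multisite harmonization of edge features,
    covariate-adjusted edge selection under leave-one-out
    cross-validation, permutation inference, consensus-network
    extraction, transfer of fitted networks to independent samples for
    replication and specificity testing, and network-anatomy summaries
    (node degree, within/between-network edge counts).  A synthetic
    multi-site generator with planted edge-behaviour effects supports
    end-to-end validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    sva,
    jsonlite
Config/testthat/edition: 3
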