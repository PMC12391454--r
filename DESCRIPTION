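Package: siteshift
Title: Divergence Heuristics and Transfer Experiments for Multi-Site
    Clinical Text Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how free-text procedure-code classifiers
    generalize across healthcare institutions. Provides a synthetic
    multi-institution corpus generator with controllable label and
    vocabulary shift, three cumulative levels of clinical text
    preprocessing (minimal cleanup, dictionary/edit-distance spelling
    correction, acronym expansion), corpus divergence statistics
    (directed vocabulary overlap, Jaccard similarity, Kullback-Leibler
    divergence over labels and over within-label word distributions, and
    a composite divergence), a TF-IDF feed-forward network classifier,
    pairwise/pooled/leave-one-institution-out evaluation designs, and
    k-medoid clustering of institutions with elbow model selection,
    multidimensional scaling and outlier flagging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    Matrix,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
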