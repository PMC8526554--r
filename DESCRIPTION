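Package: dynstates
Title: Dynamic Functional-Connectivity Brain States and Graph-Theory
    Markers of Treatment Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for resting-state ROI time series: static and
    sliding-window (tapered, L1-regularised) functional connectivity,
    k-means decomposition of windowed connectivity into recurring brain
    states with silhouette and BIC model selection, binary graph metrics
    (global efficiency, assortativity, clustering, betweenness,
    small-worldness) over a proportional-threshold sweep summarised by
    area under the curve, and covariate-controlled partial correlations
    between network metrics and a clinical response variable with FDR
    control. Includes a synthetic cohort generator with planted Markov
    state structure and a planted metric-response association for
    validation without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
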