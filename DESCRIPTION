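Package: covnet
Title: Structural Covariance Cortical Networks from Regional Gray-Matter Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds group-level structural covariance networks from per-subject
    regional gray-matter volumes on the 90-region AAL parcellation: confound
    regression (age, sex, total gray-matter volume), interregional Pearson
    correlation matrices, sparsity thresholding into binary graphs, small-world
    metrics (clustering coefficient, characteristic path length) against
    degree-matched rewired null networks, betweenness-centrality hub detection,
    and between-group inference via Fisher-z edge comparison with false
    discovery rate control and label-permutation tests of network metrics.
    Includes a synthetic multi-group cohort generator with block and homotopic
    covariance structure so the full pipeline is testable without restricted
    clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
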