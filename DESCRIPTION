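Package: epimirnet
Title: Temporal miRNA-mRNA Bayesian Network Inference for Epileptogenesis Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers temporal miRNA-mRNA-mRNA regulatory networks from
    time-course expression profiles of epileptogenesis. Provides a
    linear-Gaussian synthetic-data generator with a planted regulatory
    network, differential-expression ingestion with Benjamini-Hochberg
    correction and a Welch-test stand-in for count-based engines,
    SAMBA-style bipartite bi-clustering of mRNAs by time-point, Gaussian-BIC
    hill-climbing Bayesian network structure learning with bootstrap
    arc-strength model averaging and highest-quartile edge filtering,
    network statistics (degree, betweenness centrality, beta-index, upset
    overlap counts), and a biologically filtered miRNA prioritisation
    cascade based on inferred targets, human orthology and seed-region
    (nt 2-8) conservation.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
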