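Package: cyclegraph
Title: Menstrual-Cycle Brain Network Topology from Phase-Based Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Longitudinal analysis of source-level MEG brain networks across
    the menstrual cycle. Builds functional connectivity with the phase
    linearity measurement (PLM) from band-limited signals, extracts
    minimum-spanning-tree topology (leaf fraction, degree divergence, tree
    hierarchy, diameter, degree, betweenness centrality), runs the
    three-time-point statistical plan (Friedman and Wilcoxon tests with
    Benjamini-Hochberg correction, hormone ANOVA with paired post hocs), and
    fits a leave-one-out cross-validated multilinear model linking sex-hormone
    changes to topological changes and psychological well-being. Includes a
    calibrated synthetic-study generator (coupled phase oscillators, hormone
    panels, well-being scores) so the full pipeline is testable without
    access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
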