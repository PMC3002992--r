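Package: thboolnet
Title: Boolean Network Dynamics of Th1/Th2 Cell Differentiation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the synchronous Boolean-network model of human T helper
    (Th1/Th2) cell differentiation. Parses signed regulatory rule files
    ("at least one activator and no inhibitors" update semantics), ships a
    curated 43-rule Th1/Th2 network, enumerates all attractors exactly via
    constant-propagation reduction and per-context successor tables, runs
    systematic in silico single-gene knockout screens under temporary and
    persisting input stimulation, classifies attractors into Th phenotypes,
    and provides a companion microarray-style expression analysis stage
    (per-disease differential expression, attractor-gene ratio correlation,
    inhibitory-pair correlations) together with synthetic data generators
    for expression studies and random Boolean networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
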