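Package: fibroDFE
Title: Discrete Finite Element Modeling of Interstitial Fibrosis in
    Cardiac Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating the electrophysiological consequences of
    interstitial cardiac fibrosis on simplex meshes. Fibrotic clefts are
    represented as infinitesimal no-flux splits introduced by duplicating
    mesh vertices, with a local graph connectivity analysis that guarantees
    a tight (non-leaking) topology even for branching fibrosis networks.
    Includes an intensity-driven stochastic generator of fibrosis networks,
    a finite element monodomain solver with the ten Tusscher 2006 human
    ventricular ionic model, conduction velocity tuning, and programmed
    electrical stimulation protocols for studying transient conduction
    block, activation delay, and reentry induction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
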