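Package: popgsp
Title: Population-Graph Spectral Ensembles for Brain Disorder Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds subject-level population graphs from resting-state
    functional connectivity (RSFC) and phenotypic data (site, sex, age),
    analyzes them with graph-signal-processing tools (combinatorial
    Laplacian, graph Fourier transform, low-pass spectral filtering),
    categorizes graphs by the frequency regime in which they classify
    best, and fuses one frequency-filtered feed-forward classifier per
    selected graph through a learnable softmax-gated ensemble head for
    binary disease classification.  Includes a seeded synthetic-cohort
    generator, stratified cross-validation, rank-based AUC and the usual
    confusion-matrix metrics, baseline graphs (fully connected, identity,
    random), and sensitivity sweeps over the filtering threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
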