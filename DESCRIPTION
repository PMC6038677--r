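Package: trilayernet
Title: Triple-Layer Heterogeneous Network Propagation for miRNA-Disease
    Association Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores candidate miRNA-disease associations by iterative label
    propagation over a triple-layer heterogeneous network that couples a
    disease-miRNA association layer with a miRNA-lncRNA interaction layer
    through integrated similarity matrices.  Provides disease semantic
    similarity from a MeSH-style disease DAG (two models and their average),
    MISIM-style miRNA functional similarity, Gaussian interaction-profile
    kernels for diseases, miRNAs and lncRNAs, the coupled propagation engine
    with convergence control, a leave-one-out and repeated k-fold
    cross-validation harness with ROC/AUC, a synthetic triple-layer network
    generator with planted cluster structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
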