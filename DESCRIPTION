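Package: cnsrepurpose
Title: CNS-Focused Network Medicine Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A network-medicine pipeline for prioritizing central nervous
    system drug repurposing candidates. Implements multi-dimensional gene
    prioritization over protein interaction networks (network plasticity,
    pathway centrality, druggability, disease proximity, temporal weighting,
    with permutation significance and bootstrap stability), multi-layer
    drug-gene network construction with random walk with restart and
    proximity scoring, rule-based and machine-learning blood-brain barrier
    penetration assessment, medicinal-chemistry adjustment with modality
    classification, tractability, P-glycoprotein liability and safety
    stratification, seeded synthetic data generators for every pipeline
    input, and an end-to-end orchestrated run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    tools,
    ranger,
    xgboost,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS,
    pROC,
    withr
Config/testthat/edition: 3
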