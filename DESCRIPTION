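Package: loopmap
Title: Cortico-Cerebellar Loop Connectivity and Preparatory-Activity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking a mesoscale cortico-cerebellar
    connectome to an electrophysiological activity map of the cerebellar
    cortex during a delayed-response licking task. Computes normalized
    mossy-fiber input and Purkinje-cell output density maps from annotated
    point clouds, splits lobules into medial/lateral sub-lobules, classifies
    regions by conjunctive input-output connectivity, and fits voxel-level
    connectivity-to-activity models. Provides spike-train trial-type
    selectivity with held-out preference determination, ramping
    classification, complex-spike response-type clustering (PCA, k-means,
    silhouette), hierarchical-bootstrap perturbation statistics with
    Benjamini-Hochberg correction, and a lagged L1-penalized Poisson GLM
    that predicts firing from video embeddings as a movement control. A
    seeded synthetic-data generator emulates the anatomical, ephys,
    behavioral and embedding data structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
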