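Package: fusecyto
Title: Multiview Self-Organizing Map Clustering for Imaging Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Cell-type clustering for highly multiplexed in situ imaging
    cytometry (IMC, MIBI-TOF, CODEX, seqFISH) expression matrices. Trains a
    batch self-organizing map whose grid size is chosen by a sequential
    Tracy-Widom test on covariance eigenvalues, computes Pearson, Spearman,
    cosine and Euclidean dissimilarities between the prototypes, fuses them
    by weighted multiview integration, and clusters the fused dissimilarity
    with average-linkage hierarchical clustering before projecting labels
    back to cells. Also provides the external evaluation indices (adjusted
    Rand index, normalized mutual information, Fowlkes-Mallows, pairwise
    F-measure), six cluster-number estimators (gap, silhouette, jump, slope,
    within-cluster distance elbow, and a discriminant-projection dip-test
    method), a synthetic cytometry generator with per-cell intensity-scaling
    artifacts, and resampling/benchmarking harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
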