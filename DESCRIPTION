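Package: cci
Title: Consensus Clustering-Based Imputation of Dropouts in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes dropout zeros in single-cell RNA-seq expression matrices by
    consensus clustering: genes are repeatedly subsampled, each subset is embedded
    (PCA then UMAP) and clustered (K-means or shared nearest-neighbor), and the
    co-membership frequencies across runs define cell-to-cell similarity weights
    used to fill zero entries with (un)weighted neighbor averages. Includes a
    Splat-style synthetic count generator with mean-dependent logistic dropout,
    Seurat-style log normalization and variable-gene selection, shared
    nearest-neighbor graph clustering, and an evaluation suite (adjusted Rand
    index, compactness, Wilcoxon rank-sum differential-expression calling,
    Jaccard/sensitivity/specificity, per-gene Spearman recovery) with a
    simulation benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    uwot,
    RANN,
    irlba,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
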