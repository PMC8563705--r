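Package: omiclust
Title: Multi-Omics Cancer Subtyping via Perturbation Clustering and
    Randomized SVD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative subtyping of patients from multiple omics layers
    (mRNA, DNA methylation, miRNA, copy number). Each layer is projected to a
    low-dimensional space with a randomized singular value decomposition,
    partitioned by perturbation clustering (the number of clusters is chosen
    by stability of the pairwise connectivity matrix under repeated Gaussian
    perturbation), and the per-layer connectivity matrices are averaged into
    a single similarity matrix that is partitioned by an ensemble of
    similarity-based clusterers ranked by agreement with the per-layer
    partitions. Cohorts larger than a sampling threshold are handled by
    subtyping a sampled subset and propagating labels to the remaining
    samples with an exact k-nearest-neighbour classifier whose k is chosen
    by cross-validation. Includes a synthetic multi-omics generator and
    survival-based evaluation utilities (Cox proportional-hazards
    likelihood-ratio p-values, adjusted Rand index, normalized mutual
    information).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    data.table,
    jsonlite,
    stats,
    survival,
    utils,
    withr
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
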