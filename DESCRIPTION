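Package: seqmds
Title: Interpolative Multidimensional Scaling for Clustering Large Sequence Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clustering pipeline for large collections of short nucleotide
    reads (for example environmental 16S rRNA amplicons). Pairwise genetic
    distances are computed by Needleman-Wunsch global alignment with affine
    gap penalties, embedded into low-dimensional Cartesian coordinates by
    SMACOF stress majorization, and clustered by k-medoids on the distance
    matrix. The package's central feature is interpolative multidimensional
    scaling: a small in-sample subset is embedded by full MDS and the
    remaining out-of-sample reads are placed one at a time against their
    nearest in-sample anchors, reducing the cost of the distance and scaling
    computation from O(N^2) to O(M^2 + (N-M)*M) while preserving the cluster
    structure of the full embedding. Includes seeded synthetic-data
    generators (sequence families and exactly embeddable geometric
    fixtures), Procrustes and adjusted-Rand comparison utilities, cost
    accounting of every alignment and majorization iteration, and a
    command-line interface over the full and interpolative pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    cluster,
    mclust,
    Biostrings,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
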