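Package: seqsetdist
Title: Spectral Distance, Classification and Clustering of Heterogeneous
    Sequence-Sets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Alignment-free comparison of heterogeneous sequence-sets
    (composite data points such as segmented viral genomes). Each set is
    embedded in a word-count feature space, optionally passed through a
    linear or non-linear transformation, and summarized by its
    variance-covariance structure; the distance between two sets is the
    largest-magnitude eigenvalue (spectral norm) of the difference of
    their covariance matrices, which is a metric and requires no matrix
    inversion, so singular covariance matrices are handled natively.
    Includes nearest-class mean/min/median classification rules with
    Chebyshev consistency diagnostics, distance-based hierarchical
    clustering with 2D projections and exact/limiting dispersion maps,
    and a seeded multinomial simulator of sequence-sets with a length
    factor controlling convergence of nucleotide composition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
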