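Package: temposig
Title: Temporal Clustering and Jackstraw Evaluation of Omics Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A platform for extracting temporal signatures from omics
    time-course matrices (e.g. protein post-translational modification
    occupancy measured over days of disease progression). Provides joint
    missing-data imputation and denoising by cubic smoothing splines with
    cross-validated degrees of freedom or by reduced-rank PCA (iterative
    SVD imputation, NIPALS), unsupervised temporal clustering by K-means
    or hierarchical clustering (Euclidean or dynamic time warping
    distance) with within-cluster sum-of-squares scree support, a
    jackstraw test of cluster membership yielding empirical p-values,
    local false discovery rates and posterior inclusion probabilities,
    and a cluster-by-biological-function over-representation summary
    using hypergeometric tests with Benjamini-Hochberg correction.
    Includes seeded synthetic-data generators so every stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
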