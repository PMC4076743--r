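Package: parcelbench
Title: Benchmarking Brain Parcellations with Mixed-Effects Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Derives parcellations of a voxel domain from multi-subject
    functional contrast images using four clustering algorithms (k-means on
    PCA-reduced signals, spatially constrained Ward agglomeration, spectral
    clustering on a functionally weighted voxel adjacency graph, and purely
    geometric clustering), scores any fixed parcellation with a per-parcel
    Gaussian mixed-effects model (within- and between-subject variance
    components estimated by EM), and selects the number of parcels by BIC,
    cross-validated log-likelihood, or bootstrap reproducibility measured
    with the adjusted Rand index and adjusted mutual information. Includes a
    2D multi-subject image simulator with spatial jitter and Gaussian
    smoothing, and an orchestrated simulation study contrasting the liberal
    behaviour of accuracy-based criteria with the conservative behaviour of
    reproducibility-based criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
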