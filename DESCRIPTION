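Package: popmanifold
Title: Manifold Analysis of Neural Population Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised manifold analysis of calcium-imaging population
    recordings from head-fixed mice performing a go/no-go task: intrinsic
    dimensionality estimation from two-nearest-neighbor distance ratios,
    two-round Laplacian-eigenmaps embedding, persistent-homology comparison
    of manifold shape, central-point-cloud consensus clustering,
    mutual-information parameterization of the manifold by behavioral
    variables, trial cluster-sequence analysis, cross-dataset cluster-label
    translation and single-trial outcome decoding, and lick-train analysis.
    Ships a synthetic-session generator with known latent ground truth so
    the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    igraph,
    methods,
    vegan,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
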