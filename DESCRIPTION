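Package: gmvnmf
Title: Graph-Regularized Multi-View Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint factorization of several non-negative data views measured on
    the same samples and features, as arises when gene expression, copy-number
    and methylation profiles are available for one patient cohort. The core
    model factors each view X_I as W U_I V with a shared basis W for sample
    clustering and a shared coefficient matrix V for co-differential gene
    ranking, optionally regularized by per-view K-nearest-neighbor graph
    Laplacians so that neighboring samples receive similar latent profiles.
    Also provides the joint, integrative and orthogonality-regularized NMF
    baselines, multiplicative-update solvers with objective tracking, grid
    search over ranks and regularization strength, clustering evaluation
    (accuracy under optimal label matching, pairwise recall/precision/F),
    feature ranking from the shared coefficients, a synthetic multi-view data
    generator with planted ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
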