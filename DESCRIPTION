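Package: fpseg
Title: Exact Changepoint Detection by Pruned Dynamic Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact solvers for the multiple-changepoint segmentation of
    univariate signals such as DNA copy-number profiles. Implements the
    penalised problem via Optimal Partitioning, PELT (inequality-based
    pruning) and FPOP (functional pruning), and the constrained problem
    via Segment Neighbourhood Search, SNIP (inequality-based pruning) and
    pDPA (functional pruning), for Gaussian change-in-mean and Poisson
    change-in-rate losses. Includes pruning diagnostics, brute-force
    optimality oracles, a piecewise-constant signal simulator, robust
    MAD standardisation, penalty construction and model selection over
    the number of changes, plus plain-text/bedGraph input and CSV/BED
    segmentation output with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
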