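Package: mnlnet
Title: Brain Covariance Network Estimation by Maximising the Network Likelihood
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates a binary structural covariance network among brain
    regions of interest as the adjacency matrix of a Leroux-type multivariate
    conditional autoregressive (CAR) model, by greedy single-edge maximisation
    of the network likelihood (MNL) with multi-restart. Includes the two
    standard comparator estimators (Pearson pairwise correlation thresholding
    and graphical-lasso binarisation), a simulation framework for assessing
    network recovery (sensitivity and specificity) across sample sizes,
    covariate residualisation for region-of-interest tables, and Moran's I
    residual diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
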