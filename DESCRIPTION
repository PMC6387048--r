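Package: rpotatoes
Title: Unsupervised Multichannel Sleep-EEG Artifact Detection on the SPD Manifold
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects artifacts in multichannel sleep EEG without supervision by
    mapping short epochs to spatial covariance matrices on the manifold of
    symmetric positive-definite (SPD) matrices under the affine-invariant
    (Fisher) metric. Clean activity is summarised by several clusters
    ("Riemannian potatoes") built with Riemannian k-means, the number of
    clusters being selected by a normality criterion on standardized
    within-cluster distances (D'Agostino K2 combined with Stouffer's method).
    A sliding window is scored by its standardized Riemannian distance to the
    nearest cluster centroid, scores are interpolated, smoothed and segmented,
    and supra-threshold segments lasting at least a minimum duration are
    reported as artifacts. Includes a fuzzy-border sample-wise evaluation
    (Cohen's kappa, agreement, sensitivity, false discovery rate), a synthetic
    sleep-EEG generator with ground-truth masks, EDF and CSV input/output, and
    a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    tibble,
    ggplot2,
    generics,
    withr,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
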