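Package: MMkmeans
Title: Metric-Matrix k-Means Clustering with Whole-Cluster Stability Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements MMk-means, a k-means variant for large expression
    matrices that detects when whole clusters have stabilised by monitoring
    eigenvalues of a Pearson-correlation metric matrix computed between
    successive centroid sets, and freezes stable clusters so their members
    skip further distance evaluations. The switch-on iteration is estimated
    from a spectral lower bound on the optimal k-means objective (top-k
    squared singular values of the data matrix). Also provides the
    Traditional (Lloyd), Overlapped and Enhanced k-means baselines with
    distance-evaluation accounting, a seeded Gaussian-mixture and periodic
    expression-profile simulator, Hubert-Arabie adjusted Rand index
    evaluation, readers and writers for tab-delimited expression matrices,
    partitions and run traces, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
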