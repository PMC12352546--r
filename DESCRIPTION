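Package: fcprom
Title: Information-Theoretic Prominence of A Priori Functional Networks
    in Weighted Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how prominent a fixed, a priori node partition
    (e.g., resting-state functional networks) is in a weighted functional
    connectome, via stochastic block model parameter inference and the
    signal-to-noise ratio statistic SNR = lambda2^2 / lambda1 of the
    community profile matrix, with SNR > 1 as the weak-recovery
    (Kesten-Stigum) criterion. Implements a threshold-optimization
    pipeline for cohorts of connectomes (group-average vetting, the
    weak-recoverability threshold interval, per-subject and group-average
    optimal thresholds), size-preserving partition-shuffle null models,
    and a back-test against modularity maximization scored by adjusted
    mutual information. Includes seeded generators for planted-partition
    graphs and connectome-like weighted cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
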