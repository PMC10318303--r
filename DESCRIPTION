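Package: connectopls
Title: Behavioral Partial Least Squares and Segregation Analysis of
    Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multivariate analysis of resting-state functional connectomes
    in relation to subject-level variables such as age and dopamine
    D1-receptor availability. Implements behavioral partial least squares
    (PLS) on variables-by-edges correlation matrices with permutation tests
    on singular values and bootstrap ratios for edge-level inference, a
    system-segregation statistic on network-partitioned graphs, a
    node-label permutation test for network-block effects, simplified fMRI
    timeseries cleaning (simultaneous nuisance and band-pass regression,
    motion-spike censoring) and graph construction via Fisher-z Pearson
    correlations, downstream regression and covariate-adjusted group
    comparisons, and a synthetic cohort generator with planted,
    recoverable age and receptor effects for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
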