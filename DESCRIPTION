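Package: hierseq
Title: Hierarchical Predictive Auditory Sequence Analysis for ECoG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of electrocorticography (ECoG)
    recordings under the auditory local-global oddball paradigm. Generates
    trial sequences with nested (tone-level and sequence-level)
    regularities, synthesizes ground-truthed multichannel recordings with
    1/f background and condition-locked oscillatory components, and
    analyses them with multitaper time-frequency decomposition,
    cluster-based permutation statistics, rank-1 parallel factor analysis
    (PARAFAC) of spatio-spectro-temporal patterns, and within-/across-trial
    correlations of per-trial component contributions.
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
    yaml
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
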