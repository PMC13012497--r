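Package: dreamdepth
Title: Mixed-Model and Cluster-Permutation Analysis of Subjective Sleep Depth
    in Serial-Awakening hdEEG Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for serial-awakening high-density EEG
    studies of subjective sleep depth. Extracts Welch band-power features
    (delta, gamma, gamma/delta ratio) from pre-awakening EEG, fits linear
    mixed-effects models with a participant random intercept per electrode,
    corrects topographic maps with cluster-mass permutation testing,
    analyses dream-report taxonomies with FDR-corrected pairwise contrasts,
    summarises dream phenomenology by principal components, and models
    time-of-night trajectories with BIC polynomial order selection. Includes
    a synthetic cohort generator emulating the design of a two-experiment,
    44-participant N2 serial-awakening study so the full pipeline is
    testable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    igraph,
    pracma,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
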