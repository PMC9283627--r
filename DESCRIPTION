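Package: giscreen
Title: Quantitative Epistasis Mapping for Conjugation-Based Genetic
    Interaction Screens in Two Growth Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores double-mutant colony fitness from arrayed bacterial
    genetic-interaction screens under a multiplicative expectation and a
    Gaussian-process surface model, calls static aggravating and
    alleviating interactions with dual-model agreement at two-standard-
    deviation thresholds, builds a differential (condition-rewiring)
    network from the score difference between rich and minimal medium
    with an empirical split-half null, and provides the downstream
    network statistics used in transcription-factor epistasis studies:
    hypergeometric process-crosstalk enrichment with Benjamini-Hochberg
    correction, permutation module-crosstalk Z-tests, interaction-profile
    correlation and cross-condition autocorrelation, hub detection,
    phylogenetic-profile co-conservation, and alignment-based paralog
    filtering. A seeded synthetic screen generator with planted ground
    truth makes every stage testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tidyselect,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
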