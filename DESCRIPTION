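Package: ktnfpt
Title: First-Passage-Time Analysis of Kinetic Transition Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes the funnel organisation of molecular energy landscapes from
    first-passage-time (FPT) statistics on kinetic transition networks (KTNs).
    Provides exact spectral FPT distributions from the absorbing master equation,
    observation-time-truncated mean first passage times, standard rejection-free
    and leapfrog kinetic Monte Carlo samplers with recrossing-count acceleration,
    graph-transformation reference MFPTs, a synthetic multifunnel landscape
    generator, PATHSAMPLE-style I/O, and disconnectivity-tree diagnostics that
    connect peaks and steps in the FPT distribution to kinetic traps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
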