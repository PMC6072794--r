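Package: conetstab
Title: Stability Analysis of Microbial Co-Occurrence Networks Under Disturbance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how soil microbial co-occurrence networks respond
    to disturbances such as drought. Implements the full analysis chain from OTU
    count tables onward: rarefaction and diversity-based quality filters, Shannon
    diversity and Pielou evenness, Bray-Curtis resistance/resilience statistics,
    principal coordinates analysis and PERMANOVA, Dufrene-Legendre indicator value
    (IndVal) analysis with permutation significance and drought tolerant/sensitive
    classification, all-pairs Spearman correlation sets, thresholded positive
    co-occurrence networks with degree, betweenness, transitivity and
    Girvan-Newman modularity, Erdos-Renyi random-graph null comparisons, and the
    chi-square, ANOVA and regression comparisons used to contrast communities.
    Ships a latent-factor synthetic OTU table generator with planted modules,
    antagonistic couplings and treatment responders, providing ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
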