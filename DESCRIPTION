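Package: metafrag
Title: Fragility of Meta-Analyses with Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the fragility of pairwise meta-analyses of
    two-arm studies with binary outcomes. Computes study-level effect sizes
    (odds ratio, relative risk, risk difference) with continuity correction,
    pools them under fixed-effect and random-effects models with
    DerSimonian-Laird or restricted maximum-likelihood heterogeneity
    estimation and normal or Hartung-Knapp-Sidik-Jonkman confidence
    intervals, and derives the fragility index and fragility quotient of a
    meta-analysis by a minimum event-status-modification search (greedy,
    with an exact breadth-first oracle). Also provides the fragility
    improvement metric comparing a meta-analysis with its included studies,
    a five-scenario comparison framework, corpus-level summaries, and a
    seeded generator of Cochrane-like synthetic corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
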