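Package: planktraits
Title: Trait-Based Functional Group Analysis of Mesozooplankton Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trait-based analysis of mesozooplankton community
    structure: binary (one-hot) coding of categorical functional traits
    (body length class, feeding type, trophic group, reproductive mode),
    Gower dissimilarity between trait profiles, Ward agglomerative
    clustering with elbow selection of the number of functional groups,
    dominance screening of taxa (abundance share times occurrence
    frequency), trait and functional-group composition by season and
    station, and redundancy analysis of log-transformed group abundances
    against hydrographic variables. Includes a seeded simulator of
    seasonal cruise data with planted group-environment couplings for
    validation, and a packaged fixture derived from published seasonal
    summaries for the South Yellow Sea.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    mclust,
    cluster,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
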