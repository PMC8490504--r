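Package: trpflux
Title: Multiplexed Serum Tryptophan-Metabolite Quantitation and Kynurenine
    Pathway Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed isobaric-label (TMT sixplex)
    quantitation of serum tryptophan and its kynurenine-pathway metabolites
    with a pooled-reference design: reporter-area quality control and
    low-quality reference replacement, construction of the log2
    sample/reference ratio matrix, per-metabolite linear modelling with
    empirical-Bayes moderated t-statistics, the enzymatic-distance
    fold-change gradient, clinical association statistics (mean ratios,
    pooled t-tests, univariate Cox regression, robust FDR-based outlier
    removal), and an expression-scaled Michaelis-Menten kinetic model of the
    kynurenine pathway with steady-state concentrations and fluxes. A
    synthetic-data generator reproduces the statistical structure of the
    study design (plex layouts, channel and plex batch effects, graded
    tumor-vs-control effects, clinical covariates) so that every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
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
    utils,
    yaml
Suggests:
    limma,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
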