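Package: lignflux
Title: Compartmental Steady-State Flux and 13C-Label Analysis of Lignin Biosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble estimation of underdetermined steady-state flux
    distributions in compartmental models of monolignol biosynthesis.
    Pathway networks with cytosol and endoplasmic-reticulum pools are
    parameterized by flux split ratios at diverging branch points,
    sampled by Monte-Carlo, and filtered against lignin composition and
    13C label-incorporation observations.  Bidirectional diffusion
    fluxes between parallel metabolite pools are resolved from isotope
    balance equations, every flux is decomposed into labeled and
    unlabeled components, and admissible ensembles are summarized as
    boxplot-style distributions.  Ships encodings of an illustration
    network and three Brachypodium distachyon pathway schemes, a
    constraint table of published composition and labeling data, and a
    synthetic-experiment generator for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
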