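Package: fdtox
Title: QSAR Screening of Fullerene Derivatives for Aquatic-Toxicity-Related
    Protein Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to model the protein-binding profiles of fullerene
    derivatives and screen them for aquatic-toxicity structural alerts.
    Provides a seeded synthetic compound-table generator, topological and
    drug-like molecular descriptors, a SMILES-fragment Monte-Carlo optimal
    descriptor (DCW) engine, a counter-propagation artificial neural network
    (Kohonen input layer with a superimposed output layer) with leave-one-out
    cross-validation, an ordinary-least-squares model registry with R2/Q2
    metrics, a leverage-based applicability domain (Williams plot), a local
    SMARTS structural-alert library for aquatic toxicity, and an end-to-end
    pipeline that ranks compounds by predicted binding score annotated with
    alerts and domain flags.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
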