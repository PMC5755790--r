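Package: fluxwindow
Title: Expression-Constrained Flux Balance Screening for Drug
    Therapeutic Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Integrates RNA-seq expression profiles with genome-scale
    metabolic models to predict differential drug effects on cell
    growth. Expression levels (RPKM) are converted into reaction flux
    bounds by a discretized proportionality rule, maximal biomass
    production is computed by linear programming, and competitive
    inhibition of drug-targeted reactions is simulated as a fractional
    tightening of their baseline rates. Drug-to-enzyme target mapping
    uses substructure-key fingerprint similarity (Tanimoto) between
    drugs and endogenous metabolites, with shared-EC-number enrichment
    statistics against a bootstrap null. A screening layer ranks
    therapeutic windows: drugs predicted to impair growth of cancer
    expression profiles more than healthy ones. Includes synthetic
    fixture generators (toy SBML models, planted-window expression
    profiles, toy compound libraries) and brute-force linear-programming
    oracles so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
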