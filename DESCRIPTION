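Package: proload
Title: Protein-Production Load Analysis for Filamentous-Fungus Batch Cultivations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying the metabolic load of
    extracellular protein production in filamentous-fungus batch bioreactor
    cultivations. Concentration and biomass time series are interpolated with
    heteroscedastic Gaussian processes whose analytic derivative posterior
    yields specific uptake, secretion and growth rates; gene-expression
    profiles are screened against cultivation parameters with Spearman
    correlation under Storey q-value FDR control; profiles are grouped with
    Bayesian hierarchical clustering; annotation terms and metabolic pathways
    are tested with the hypergeometric test; and condition-specific flux
    balance analysis (FBA, parsimonious FBA, flux variability analysis) of a
    stoichiometric model with an amino-acid-composition protein objective
    predicts the extracellular protein production rate. A synthetic-data
    module generates Monod-type batch trajectories, expression matrices with
    planted correlations and small stoichiometric networks with known optima
    so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    boot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
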