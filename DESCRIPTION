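Package: cardiomet
Title: Tissue Metabolomics and Cardiomyocyte Flux Modelling for the RUPP
    Preeclampsia Model
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-group (sham vs RUPP)
    tissue metabolomics by 1D 1H NMR: seeded synthetic data generation
    (concentration tables, free induction decays, toy metabolic networks),
    FID processing and TSP-referenced quantification per gram wet weight,
    normality-routed two-group statistics with derived energetic indices
    and delta-delta-Ct fold changes, metabolite co-regulation networks
    with eigenvector centrality, and metabolite-constrained flux balance
    analysis of a reduced compartmentalized cardiomyocyte network with
    PCA, hierarchical clustering and subsystem enrichment of flux
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
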