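Package: cdbind
Title: QSAR Modeling of Phenolic-Acid Binding to Beta-Cyclodextrin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structure-activity relationship (QSAR)
    modeling of host-guest binding between beta-cyclodextrin and small
    phenolic guests. Computes a focused set of molecular descriptors
    (ring counts, Broto-Moreau and Geary topological autocorrelations,
    Burden and edge-adjacency eigenvalues, the Kier alpha-modified shape
    index, GETAWAY H autocorrelations, 3D-MoRSE signals and topological
    polar surface area) from SMILES or SDF input, performs genetic-algorithm
    descriptor selection scored by multiple linear regression with
    leave-one-out cross-validation, reports the standard QSAR validation
    battery (R2, RMSE, MAE, Lin's concordance, F, Q2), assesses the
    applicability domain via leverages and standardized residuals
    (Williams plot), and ships a packaged 20-ligand data set of docking
    scores and semi-empirical binding affinities together with three
    frozen published model equations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    stats,
    utils,
    tools,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
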