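Package: pharmscreen
Title: Structure-Based Pharmacophore Screening and Dose-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An integrated virtual-screening pipeline for receptor-based
    drug discovery: hydrogen-bond contact detection in receptor-ligand
    complexes, structure-based pharmacophore model construction,
    Guener-Henry (GH) enrichment scoring against active/decoy sets,
    Lipinski rule-of-five filtering, all-feature pharmacophore matching by
    rigid-body superposition RMSD, and four-parameter logistic (4PL)
    dose-response fitting with IC50 and target-selectivity estimation.
    Includes a synthetic-data module that generates toy receptor-ligand
    complexes, screening libraries with planted actives, and simulated
    uptake-inhibition assays with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    bio3d,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
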