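Package: icasflow
Title: Desk-Scale Hemodynamics of Intracranial Atherosclerotic Stenosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates steady, incompressible, Newtonian blood flow through
    parametric stenosed vessels at middle-cerebral-artery scale, extracts wall
    shear stress and wall pressure along the lesion's prominent side, computes
    translesional indices (WSS ratios, FFR-like pressure ratio, segmental
    pressure drops) at five defined measuring points, and runs the cohort
    statistics (Friedman, Wilcoxon post-hoc with Bonferroni correction,
    chi-square, Cohen's kappa, plain and covariate-adjusted Spearman rank
    correlation) used to characterise how these indices vary with percent
    stenosis in intracranial atherosclerosis. Includes a seeded synthetic
    lesion-cohort generator standing in for patient angiography and
    ultrasonography, an axisymmetric streamfunction-vorticity finite-difference
    flow solver with an optional planar mode for eccentric plaques, and an
    end-to-end study pipeline with CSV/VTK/YAML outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
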