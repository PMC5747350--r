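Package: cholode
Title: Logic-Based ODE Modeling of Cellular Cholesterol Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-line-specific logic-based ordinary differential equation
    modeling of cellular cholesterol regulation. Encodes a signed prior-knowledge
    network of sterol sensing (SREBP/LXR), cholesterol synthesis and uptake as a
    hybrid system of normalized-Hill relaxation dynamics and explicit metabolic
    rate laws, scales perturbation-response measurements to the unit interval in
    MIDAS-backed containers, fits bootstrap ensembles of parameter sets with a
    seeded global optimizer and an adapted weighted least-squares objective, and
    compares parameter ensembles across cell lines with effect-size and rank-test
    statistics. Also implements the accompanying mass-spectrometry post-processing
    statistics: decoy-based FDR estimation, presence filtering, proteotypic
    peptide selection, total-intensity normalization, differential-abundance
    decision rules, nested ANOVA, and exact-mass metabolite annotation. A
    synthetic-data generator emulates the perturbation study design so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
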