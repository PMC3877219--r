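Package: amideshift
Title: Amide Proton Chemical Shift Prediction and Hydrogen-Bond Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts protein backbone amide proton chemical shifts as a sum
    of additive, quantum-chemistry-motivated terms (a phi/psi cosine-series
    backbone term, closed-form and lookup-table hydrogen-bond perturbations,
    and a point-dipole ring-current term), back-calculates trans-hydrogen-bond
    h3J(NC') scalar couplings and N-H residual dipolar couplings (with
    SVD-fitted alignment tensors and Q-factors), and refines hydrogen-bond
    geometries by Metropolis-Hastings sampling from a Bayesian posterior that
    combines a pluggable prior energy with a per-bond-class Gaussian
    chemical-shift likelihood. Includes generators for ideal secondary
    structure peptides, amide-dimer geometry scans and synthetic observable
    tables used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
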