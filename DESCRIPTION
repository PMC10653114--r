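Package: neqpka
Title: Protein pKa Prediction from Nonequilibrium Alchemical Work Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for predicting protein residue pKa values from
    nonequilibrium alchemical free energy calculations. Ingests per-transition
    dH/d-lambda curves or pre-integrated work values, estimates deprotonation
    free energies with the Bennett acceptance ratio (the maximum-likelihood
    estimator under the Crooks fluctuation theorem) with bootstrap
    uncertainties, assembles the protein-versus-peptide thermodynamic cycle to
    convert double free energy differences into pKa shifts relative to class
    reference values, resolves coupled titratable sites with a pH-dependent
    microstate model, and scores predictions against experiment with average
    unsigned error and Pearson statistics. A synthetic generator produces
    Crooks-consistent forward/reverse work distributions and full residue
    datasets with known ground truth in place of molecular dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
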