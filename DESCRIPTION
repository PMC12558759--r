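Package: matrinepk
Title: Minimal Physiologically Based Pharmacokinetics of Matrine in the
    Pig Intestinal Lumen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation, parameter estimation and dosage-regimen
    evaluation for a minimal four-compartment, flow-limited physiologically
    based pharmacokinetic (PBPK) model of the alkaloid matrine in the pig
    intestinal lumen after oral dosing. Includes non-compartmental analysis
    (Cmax, Tmax, trapezoidal AUC, terminal slope, half-life, MRT, CL/F, V/F),
    Nelder-Mead maximum-likelihood parameter estimation with normalized
    sensitivity coefficients, predicted-versus-observed evaluation
    statistics, steady-state time-above-threshold PK/PD metrics, and a
    synthetic cohort generator with inter-individual variability, residual
    error and censoring at the assay quantification limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
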