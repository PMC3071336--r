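Package: iosmodel
Title: Equivalent-Circuit Modelling of Impulse Oscillometry Lung Function Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing impulse oscillometry (IOS) respiratory
    impedance spectra with lumped-parameter equivalent electrical circuit
    models. Evaluates the extended RIC (eRIC) and augmented RIC (aRIC)
    circuit impedances, estimates their parameters (central resistance Rc,
    inertance I, peripheral resistance Rp, peripheral compliance Cp,
    extrathoracic shunt compliance Ce) from measured resistance/reactance
    spectra by bounded multi-start nonlinear least squares, and computes the
    hallmark IOS indices R5, R20, fdR (R5 - R20), X5, resonant frequency and
    reactance area (AX). Includes a synthetic-cohort generator emulating a
    paediatric study design (healthy versus small-airway-impaired groups,
    two visits, pre/post bronchodilator conditions) and cohort-level
    statistical reporting: group means, growth and bronchodilator percent
    changes, paired and Welch t-tests, and parameter-index correlations.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
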