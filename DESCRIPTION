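Package: nanofet
Title: Analytical Sensitivity Modelling of Nanowire Field-Effect Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts the conductance response of semiconducting nanowire
    field-effect (BioFET) sensors to the binding of charged biomolecules.
    Builds a pH-dependent discrete charge distribution from a protein
    structure (Henderson-Hasselbalch protonation of ionizable residues and
    chain termini, coarse-grained placement at side-chain terminal atoms),
    orients it over the wire, and evaluates the relative conductance change
    with an analytical screening model: Thomas-Fermi screening of the
    carrier gas inside the wire, an unscreened oxide shell, and Debye
    screening in the electrolyte, solved in cylindrical coordinates with
    modified Bessel functions. Includes parameter sweeps, pH-response
    curves, nanowire coverage estimation, and least-squares fitting of the
    average analyte charge height from the Debye-length dependence of the
    relative sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
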