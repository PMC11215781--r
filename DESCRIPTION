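Package: ramaspec
Title: Spectroscopic Assessment of Ramachandran Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for judging backbone conformational ensembles of short
    peptides against NMR and vibrational spectroscopy. Represents Ramachandran
    distributions either as periodic two-dimensional Gaussian mixtures or as
    2-degree histograms built from dihedral time series, computes mesostate
    (pPII, beta, alpha) populations with optional chirality symmetrization,
    ensemble-averages Karplus-equation J-coupling constants with Gaussian
    error propagation, simulates amide I' IR, Raman and VCD band profiles with
    a two-oscillator transition-dipole exciton model, scores ensembles with
    reduced chi-square statistics, and detects geometric hydrogen bonds with
    block-averaged uncertainties.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
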