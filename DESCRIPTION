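Package: elfiqa
Title: Electron-Pair Basin Analysis of Aromatic Substituent Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the electron localization function (ELF) from
    single-determinant wavefunctions (Molden, AIM wfn/wfx), partitions
    space into electron-pair basins on a uniform grid, integrates basin
    populations, positive-definite kinetic energies and domain overlap
    matrices, derives delocalization indices and inter-basin interacting
    quantum atoms (IQA) energy components, and assembles descriptors of
    substituent effects in electrophilic aromatic substitution: ring bond
    populations, vicinal delocalization indices, kinetic energy per
    electron, orientation prediction, and Hammett correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
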