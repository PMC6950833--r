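Package: cavclamp
Title: Voltage-Clamp Simulation and Gating Analysis for Cav1.3 Channel Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize gain- and loss-of-function phenotypes of
    Cav1.3 (CACNA1D) L-type calcium-channel missense variants from whole-cell
    voltage-clamp data. Provides constructors for the standard stimulation
    protocols (current-voltage grids, steady-state inactivation, tail-current,
    pharmacology and action-potential-waveform trains), a kinetic gating
    simulator that generates synthetic whole-cell recordings for wild-type and
    mutant channels, preprocessing (liquid-junction correction, offline and
    P/4 leak subtraction, current-density normalization, amplitude-window
    quality control), Boltzmann fits of activation and steady-state
    inactivation, window currents, decomposition of voltage- and
    calcium-dependent inactivation, bi-exponential tail-current kinetics, an
    open-probability proxy from gating charge and tail currents,
    run-down-corrected Hill dose-response fits with curve comparison,
    calcium-charge analysis of action-potential trains, and a rule-based
    gain/loss-of-function classifier with report output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
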