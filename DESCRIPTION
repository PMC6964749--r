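Package: vmatqa
Title: Complexity, Deliverability and Plan-Quality Analysis for VMAT Treatment Plans
Version: 0.1.0
Authors@R:
    person("vmatqa", "maintainers", email = "vmatqa@example.org", role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance of volumetric
    modulated arc therapy (VMAT) treatment plans. Reads DICOM RT Plan files
    into a validated arc/control-point model, computes standard plan
    complexity metrics (monitor units per Gy, modulation complexity score,
    edge metric, mean leaf motion per degree of gantry rotation), performs
    2D gamma-index comparisons of computed versus measured dose planes with
    global or local normalization and TG-218 style criteria presets,
    computes dose-volume histogram quality metrics (Dx, Vx, homogeneity and
    conformity indices), derives in-field overlap volume histograms and
    library-lookup knowledge-based dose-volume predictions, and provides a
    paired-cohort statistics layer. A synthetic cohort generator emulates
    prostate-like anatomies, two-arc VMAT plans at controlled modulation,
    fluence-convolution dose surrogates, and perturbed diode-array style
    measurements so the whole pipeline can be exercised without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
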