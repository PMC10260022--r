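Package: tifmtools
Title: Quantitative Metabolomics for Interstitial-Fluid-Matched Cell Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Formulates and verifies tumor-interstitial-fluid-matched culture
    media from interstitial-fluid metabolite measurements, converts LC-MS and
    GC-MS peak areas into absolute metabolite concentrations via internal
    standards and external calibration curves, estimates per-cell metabolite
    consumption/release fluxes from paired media measurements with propagated
    standard errors, corrects mass-isotopomer distributions for natural
    isotope abundance and compares tracer enrichment between compartments,
    converts tumor amino-acid amounts into intratumoral concentrations via
    ellipsoid-based tumor density, and computes ancillary immunohistochemistry
    and qPCR scores. A synthetic-data module generates every pipeline input
    with known ground truth so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
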