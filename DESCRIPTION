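Package: bluesat
Title: Haemocyanin Oxygen Transport Analysis for Octopod Haemolymph
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse oxygen transport by octopod haemocyanin from
    diffusion-chamber experiments: simulation of chamber traces with known
    ground truth, absorbance calibration and drift correction, five-parameter
    logistic pH-oxygen-saturation curve fitting with bootstrap confidence
    intervals, derivation of P50, Bohr coefficient and cooperativity of
    oxygenation-linked proton binding, alpha-stat acid-base projection of
    haemolymph pH across temperature, seawater oxygen solubility and
    dissolved-oxygen budgets, and a circulatory supply-demand model relating
    metabolic oxygen demand (allometric and Q10 scaled) to the required
    blood-volume turnover.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
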