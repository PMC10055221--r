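Package: resstack
Title: Stacked Ensembles of Masked-Residue Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing and combining per-residue amino-acid
    predictors. Provides a tab-separated interchange format for 20-way
    per-site probability predictions, a fully connected stacking network
    (80-120-60-20, relu/softmax) trained with Adam on categorical
    cross-entropy, naive ensemble baselines (probability averaging and
    max-probability voting), an evaluation battery (per-protein accuracy,
    amino-acid-class accuracy, inter-model accuracy correlation, model
    agreement taxonomy, confidence-versus-RSA histograms), a Shrake-Rupley
    solvent-accessible surface area implementation with max-ASA
    normalization to relative solvent accessibility, homology-aware
    train/test splitting from RCSB entity cluster files, and a calibrated
    synthetic predictor-panel simulator so the whole pipeline is testable
    without any pretrained networks or structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
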