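Package: growthrelay
Title: Growth-Rate Control of the Bacillus subtilis Sporulation Phosphorelay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for growth-rate-dependent activation of the
    Bacillus subtilis sporulation master regulator Spo0A. Implements a deterministic
    ODE model of the KinA-Spo0F-Spo0B-Spo0A phosphorelay driven by replication-
    coordinated gene-dosage changes, dilution and cell-volume effects; phenomenological
    growth-physiology laws (division length, replication period, stable-protein
    accumulation) with fitting routines; a seeded generator of synthetic single-cell
    time-lapse lineage data; the single-cell quantification pipeline (instantaneous
    growth rates, promoter activities, Savitzky-Golay peak detection, binning);
    logistic-regression fate thresholds with ROC/AUC evaluation; and a Monod
    nutrient-depletion colony model with a growth-threshold sporulation-deferral
    predictor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
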