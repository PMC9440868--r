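Package: ldlemax
Title: Dose-Response Modelling and Simulation of LDL Cholesterol Lowering
    by Bempedoic Acid and Statin Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Indirect-effect Emax dose-response models for LDL cholesterol
    lowering by bempedoic acid, four statins (atorvastatin, simvastatin,
    rosuvastatin, pravastatin) and their combinations, including a bilinear
    drug-drug interaction term. Provides deterministic model algebra,
    population simulation with inter-individual variability, parametric and
    non-parametric bootstrap uncertainty, goal-attainment prediction,
    pre-statin baseline imputation, Laplace-approximation mixed-effects
    estimation with interaction-coefficient profiling, a synthetic
    trial-data generator, and report builders for percent-change, absolute
    LDL-C and target-attainment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    withr,
    pracma
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
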