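Package: fncea
Title: Cost-Effectiveness Modelling of G-CSF Prophylaxis for
    Chemotherapy-Induced Febrile Neutropenia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-phase Markov cohort model evaluating no, primary and
    secondary granulocyte colony-stimulating factor (G-CSF) prophylaxis of
    chemotherapy-induced febrile neutropenia in early-stage breast cancer,
    from a single-payer perspective. Provides an exact expected-value engine
    for the six-cycle chemotherapy phase, an annual-cycle lifetime survival
    phase with QALY discounting, cost-effectiveness frontier construction
    with extended dominance, scenario and one-way sensitivity analyses with
    threshold search, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and a synthetic-data module
    (calibrated life table and individual-level chemotherapy-cycle cohort
    simulator) for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
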