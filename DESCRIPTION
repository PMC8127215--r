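Package: careersim
Title: Career-Long Clinician Exposure to Rare Diseases by Cohort Simulation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seeded Monte Carlo simulation of the number of patients with
    conditions of widely varying prevalence that a cohort of clinicians
    encounters over entire careers. Conditions follow a decaying exponential
    prevalence curve spanning 0.641 down to one per million; spontaneous and
    congenital/persistent conditions are handled separately, with
    congenital caseloads entering only through new patients (practice
    changes and panel attrition) and persisting until the clinician changes
    practice. Includes a closed-form expected-encounter calculator that
    serves as the analytic oracle for the simulator, reporting views
    (cohort totals, first-year totals, per-clinician career tables with
    colour binning), and Pearson chi-squared analysis of grouped ordered
    survey tables. A command-line interface exposes disease-list
    generation, simulation, expectation tables and survey analysis with
    reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
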