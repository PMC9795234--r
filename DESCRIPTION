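Package: htnsim
Title: Virtual-Patient Simulation of Antihypertensive Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reduced-order, beat-averaged model of the human cardiovascular,
    renal and renin-angiotensin-aldosterone systems, driven by a
    pharmacodynamic layer for six antihypertensive drugs (aliskiren,
    amlodipine, bisoprolol, enalapril, hydrochlorothiazide, losartan).
    Provides a constrained stochastic-ranking evolution strategy, a virtual
    patient and virtual population generator with inclusion/exclusion
    criteria and a sodium-loading validity test, and a treatment pipeline
    that simulates 4-week mono- and dual therapy, calibrates per-drug
    hemodynamic gains against clinical response tables, and summarises
    population blood-pressure and heart-rate responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
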