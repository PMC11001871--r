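Package: pulsim
Title: Simulation and Recurrent Surrogate Modelling of Pulsed
    Radio-Immunotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for studying the temporal interplay between pulsed
    radiotherapy and anti-PD-L1 immune checkpoint blockade in syngeneic
    murine tumour models.  Simulates cohorts of animals under arbitrary
    pulse/drug schedules (exponential growth, linear-quadratic radiation
    kill, delayed immune-mediated killing), augments sparse group-level
    tumour-volume summaries into dense training sequences, fits a
    many-to-one long short-term memory (LSTM) surrogate of tumour volume
    change with a masked squared-error loss, probes the fitted network
    through hidden-unit difference maps, and scores hypothetical delivery
    schedules in silico by accumulated volume change (AVC).
License: MIT + file LICENSE
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
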