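Package: microturn
Title: Spatial Birth-Death Modelling of Microglial Population Turnover
Version: 0.1.0
Authors@R: person("microturn", "developers", email = "microturn@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the homeostatic turnover of tissue-resident
    cell populations such as microglia. Provides a daily-resolution spatial
    birth-death simulator with coupled proliferation and apoptosis, optional
    pulse labeling and an apoptosis-blocked scenario; closed-form pulse-chase
    labeling kinetics (cycling fraction, cell-cycle length, whole-population
    renewal time, apoptotic depletion time); per-day proliferation and death
    rate estimators for longitudinal cell-track tables, twin-pair dispersion
    profiles and nearest-neighbor spacing; spatiotemporal statistics for the
    coupling of death and proliferation events with a permutation null; and a
    command-line pipeline that reproduces the package's reference calculations.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
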