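Package: tasksetmem
Title: Spontaneous Task-Set Formation and Its Cost to Incidental Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying spontaneous hierarchical task-set formation in
    trial-and-error category learning and its consequences for incidental
    recognition memory. Generates the trial structures of four two-dimensional
    category-learning experiments (clustered versus non-clustered key mappings,
    counterbalanced versions, an implicit mid-phase rule switch), simulates
    flat and hierarchical learner agents with lognormal reaction times and
    signal-detection memory, applies the trial- and participant-level filters,
    computes signed, absolute and d-prime-normalized switch costs, infers each
    participant's supraordinate dimension, and tests structure formation with
    within-participant label-permutation nulls at the individual and group
    level. Recognition and source memory are analysed with hit and false-alarm
    rates, paired t-tests, and Greenhouse-Geisser-corrected repeated-measures
    ANOVAs with optional switch-cost covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
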