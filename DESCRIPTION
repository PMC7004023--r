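Package: erec
Title: Effective Refractive Error Coverage from Population-Based Surveys
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes effective refractive error coverage (eREC), refractive
    error coverage (REC) and the relative quality gap in refractive error
    services from individual-level population-based survey data. Visual
    acuities recorded in Snellen (6-metre or 20-foot) or logMAR notation,
    including low-vision categories, are parsed onto the logMAR scale;
    participants are classified into no-need, met, under-met, unmet,
    other-vision-impairment and indeterminate categories from uncorrected,
    corrected, pinhole and best-corrected acuity in the better eye; and
    coverage indicators are estimated with sampling weights, stratification,
    direct age-sex standardisation and Wilson or cluster-bootstrap confidence
    intervals. Includes a survey reader driven by a column-mapping
    configuration, a command-line interface, and a seeded synthetic-cohort
    generator with known true coverage for validation and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
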