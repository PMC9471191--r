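Package: adconcord
Title: Longitudinal Antidepressant Treatment Patterns and CANMAT
    Algorithm Concordance
Version: 0.1.0
Authors@R:
    person("adconcord", "maintainers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for mining longitudinal antidepressant treatment
    patterns from prescription-level electronic medical records and
    scoring their concordance with the CANMAT 2016 stepwise
    pharmacotherapy algorithm for major depressive disorder. Includes a
    new-user cohort builder (index date, one-year washout, treatment
    episodes closed by a 120-day dispensing gap), a supply-overlap
    pattern engine that classifies every medication change as a switch,
    add-on or attempt and assigns sequential treatment levels, a
    tier-table driven concordance classifier, descriptive and
    Cochran-Armitage trend statistics, and a configurable synthetic EMR
    generator with per-patient ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
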