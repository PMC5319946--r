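Package: affectscales
Title: Composite Depression and Anxiety Rating Scales for Rodent Behavioural Assays
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes behavioural indices for preclinical affect phenotyping
    (sucrose preference, von Frey 50% withdrawal threshold, open-field and
    elevated-plus-maze trajectory metrics), scores them on data-driven
    interval rating scales yielding a total depression score (0-25) and a
    total anxiety score (0-28), and compares treatment groups with one-way
    ANOVA followed by Student-Newman-Keuls multiple comparisons, two-sample
    t-tests and the Pearson correlation between the two totals.  A synthetic
    cohort generator emulating a four-group chronic-migraine design (vehicle
    control, inflammatory-soup, inflammatory-soup plus amitriptyline,
    amitriptyline alone; 21-day time course) makes the whole pipeline
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
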