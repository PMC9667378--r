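Package: mortlink
Title: Deterministic Record Linkage of Patient Registries with National
    Mortality Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic, edit-distance-based record linkage between a
    local patient registry and a national mortality file that share no
    unique identifier. Implements restricted Damerau-Levenshtein (optimal
    string alignment) field comparison with per-field and total distance
    thresholds, French-style name and city normalisation (accent removal,
    compound given names, married-name handling, district suppression,
    birth-date repair), two-pass blocking on birth date and on a 4+4
    name-prefix key, best-pair selection, a direct exact-matching reference
    strategy, stratified sensitivity/specificity evaluation with weighted
    confidence intervals and McNemar strategy comparison, and a seeded
    synthetic identity generator with an explicit error-injection model for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    parallel,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
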