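Package: occuscore
Title: Marker-Gene Scoring of Bulk Lung Transcriptomes and Calibrated
    Quantification of Marker-Positive Nuclei
Version: 0.1.0
Authors@R:
    person("occuscore", "developers", email = "occuscore@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting cell-population shifts in bulk lung
    transcriptomes by scoring cell-type marker gene sets against a control
    group (group-median relative expression with Kruskal-Wallis/Dunn rank
    statistics), for applying read-count and differential-expression
    filtering gates to gene tables, and for quantifying the fraction of
    marker-positive nuclei in fluorescence images using a negative-control
    calibrated intensity threshold with localization-aware (nuclear,
    cytoplasmic, apical) association rules. Includes seeded synthetic-data
    generators for bulk expression mixtures with known cell-type mixing
    proportions and for microscopy fields with known positive fractions,
    enabling ground-truth validation of every stage, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
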