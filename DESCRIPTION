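Package: egfrmarkers
Title: EGFR-Subtype-Stratified Immuno-Genomic Biomarker Profiling for NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a biomarker analysis pipeline for
    non-small-cell lung cancer stratified by EGFR mutation subtype: somatic
    variant filtering, EGFR subtype classification from protein-level HGVS,
    tumor mutational burden (TMB) computation with panel-versus-WES cutoff
    harmonization by reference-population quantile matching, microsatellite
    instability (MSI) scoring from per-locus read-length histograms, PD-L1
    tumor proportion score tiering, tumor-immune-microenvironment density
    quantification, and biomarker-stratified progression-free-survival
    analysis (Kaplan-Meier, log-rank, univariate Cox). A synthetic-cohort
    generator emulates the statistical structure of the study population so
    every stage is testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    survival,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
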