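Package: cisMRkit
Title: Drug-Target Mendelian Randomization with Cis Instruments
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for drug-target Mendelian randomization from GWAS summary
    statistics: parsing and allele harmonization of per-variant association
    tables, cis-window instrument selection with greedy LD clumping and
    instrument-strength diagnostics, a suite of causal-effect estimators
    (Wald ratio, fixed-effect inverse-variance weighting, MR-Egger, weighted
    median, weighted mode) with Cochran Q heterogeneity and leave-one-out
    sensitivity analyses, decrement-scaled odds-ratio reporting,
    between-outcome heterogeneity contrasts against a positive control,
    analytic power bounds for binary outcomes, and individual-level genetic
    risk score contrasts with bootstrap confidence intervals. Includes a
    synthetic-data generator that simulates LD-correlated cis regions,
    log-normal biomarkers, binary outcomes under tunable causal and
    pleiotropic effects, and biobank-style cohorts with known truth for
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: StatisticalMethod, GenomeWideAssociationStudy, SNP, Software
RoxygenNote: 7.3.3
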