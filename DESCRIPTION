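Package: bwfbiopsy
Title: Multi-Compartment Liquid-Biopsy Concordance, Tumor Burden and
    Clonal Dynamics for Small Cell Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for matched multi-compartment liquid-biopsy
    cohorts in extensive-stage small cell lung cancer: somatic call
    filtering against a matched germline sample and population-SNP lists,
    cross-compartment mutation concordance (tissue, bronchial washing
    fluid supernatant and precipitate, plasma), targeted-panel tumor
    mutational burden with TMB-high classification, per-sample VAF/MVAF
    summaries, the molecular tumor burden index (mTBI) clonality statistic
    with treatment dynamics, cohort-level rank tests, correlation and
    survival stratification, and a seeded binomial ctDNA-shedding
    simulator that generates matched synthetic cohorts plus deterministic
    count-constrained fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
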