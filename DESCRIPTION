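Package: spirogwas
Title: Stratified GWAS of Airflow Obstruction Under Two Spirometric Definitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare genome-wide association results for airflow
    obstruction defined by the fixed FEV1/FVC < 70% cut-off versus the
    LMS-based lower limit of normal (LLN) in the same population, stratified
    by smoking status. Includes LMS reference-equation evaluation and
    obstruction classification, SNP-level quality control with an exact
    Hardy-Weinberg test, additive-model logistic GWAS with Wald inference and
    genomic-inflation estimation implemented from first principles, hit-set
    overlap and agreement statistics, cohort-expansion and random
    case-allocation simulation studies, inverse-variance fixed-effects
    meta-analysis with heterogeneity and direction-of-effect encoding,
    cis-eQTL scanning, PLINK text/binary readers and writers, and a synthetic
    cohort generator that emulates the statistical structure of a
    population-based spirometry study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
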