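Package: txmarker
Title: Treatment-Success Biomarker Discovery from Expression, Methylation
    and Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens tumour cohorts for biomarkers of treatment success.
    Patient metadata, gene-level count matrices and CpG beta-value matrices
    are combined into per-cancer, per-sex and pooled basket case sets that
    are crossed with survival-time cutoffs.  Differential features between
    outcome groups are dichotomised at the mean of the outcome-group medians,
    optionally with a percent exclusion band, and assessed with Kaplan-Meier
    and Cox proportional-hazards analyses: base plots contrast high and low
    strata among treated patients, validation plots contrast treated and
    untreated patients within each stratum, and candidates are ranked by the
    product of the base and direction-matching validation p-values.  A
    seeded synthetic-cohort generator with planted treatment-specific,
    universal and null markers supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite,
    GenomicRanges,
    IRanges
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
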