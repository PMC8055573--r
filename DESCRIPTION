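Package: hypindex
Title: Hypertrophic Index Pipeline for Plasma-Treated Cardiomyocyte Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a functional biomarker assay in which
    neonatal rat cardiomyocytes are treated with patient plasma and the
    phenylephrine-induced growth response is quantified as a Hypertrophic
    Index (HI). Provides single-cell morphology quality control, per-plate
    normalization to fetal calf serum control wells, well-wise and
    patient-level HI computation, optimal-cutpoint selection for prognostic
    stratification with cluster-robust Cox proportional hazards models,
    Kaplan-Meier and uni-/multivariate survival analyses, mixed-effect group
    comparisons, and a seeded synthetic-cohort generator emulating the
    hierarchical plate/well/cell structure and time-to-event outcomes of a
    transthyretin amyloidosis cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
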