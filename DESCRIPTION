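Package: resistsig
Title: Treatment-Selected Resistance Mutations in Longitudinal cfDNA and
    Mutant-Like Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting treatment-selected resistance mutations in
    longitudinal circulating tumor DNA (relative mutant-allele-frequency
    normalization, paired baseline/end-of-study selection calling, per-gene
    treatment-arm enrichment with false-discovery-rate control, and mutation
    evolution maps), for deriving and scoring a mutant-like transcriptional
    signature (covariate/interaction differential expression, sign-oriented
    first principal component of z-scored signature-gene expression, quartile
    stratification), and for associating biomarker groups with clinical
    outcome (Kaplan-Meier, log-rank, biomarker-by-treatment interaction
    proportional-hazards models, response-rate comparison, and xenograft
    volume-change response classification). Includes fully seeded synthetic
    cohort generators that reproduce the statistical structure these analyses
    assume, so the complete chain runs without access to restricted clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    limma,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
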