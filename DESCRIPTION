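Package: organotrope
Title: Organotropism Gene Signatures, Per-Sample Enrichment Scoring and
    TCR-Beta Repertoire Analytics for Pancreatic Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives subtype-orthogonal organotropism ("pORG"-like) and
    subtype ("pSUB"-like) gene signatures from two-factor negative-binomial
    differential expression with leave-one-out cross-validation, computes
    GSVA-style kernel-CDF per-sample enrichment scores and top-scoring-pairs
    subtype calls, analyzes TCR-beta repertoires (diversity, clonality,
    overlap, tumor-distinct and shared dominant clonotypes) on matched
    blood-tumor pairs, and provides the accompanying survival and
    association statistics (Kaplan-Meier, log-rank, Cox proportional
    hazards, Youden-index dichotomization, Fisher's exact). Includes a
    synthetic-study generator with planted ground truth so every stage of
    the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    survival,
    edgeR,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
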