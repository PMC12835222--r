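Package: hemidiff
Title: Paired-Hemisphere Differential Expression and Asymmetry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for paired left/right hemisphere bulk
    RNA-seq cohorts, motivated by hemispheric asymmetry in Parkinson's
    disease. Starting from a gene-by-sample count matrix and a clinical
    sample sheet it derives severe/moderate hemisphere labels from the
    side of symptom onset, normalizes counts by trimmed mean of M-values,
    fits a two-stage moderated linear model with residual-SVD correction
    factors, tests disease and asymmetry contrasts with false discovery
    rate control, clusters subjects by rank correlation to select a
    homogeneous subset, scores per-subject directional gene-set asymmetry
    and stratifies subjects by its sign, classifies genes across
    contrasts, and runs preranked running-sum gene-set enrichment. A
    negative-binomial cohort simulator with planted effects, subject
    random effects and batch factors supports calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
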