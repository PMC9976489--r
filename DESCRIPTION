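Package: methclocks
Title: Epigenetic Clock Construction from DNA Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for building and evaluating epigenetic clocks from
    DNA-methylation beta-value matrices. Provides epigenome-wide association
    scans of chronological age (linear and quadratic M-value models with
    nested F-tests) and of time to all-cause mortality (per-CpG Cox
    proportional-hazards models), EWAS-ranked feature pre-selection,
    elastic-net chronological-age clocks with a hybrid log(age) rule for
    young predictions, projection of protein EpiScores, a penalized-Cox
    biological-age (mortality) clock with age-acceleration residuals, and an
    evaluation suite (concordance, fixed-effects meta-analysis, Schoenfeld
    proportional-hazards diagnostics, leave-one-cohort-out validation).
    Includes a synthetic-cohort generator emulating age-dependent CpG
    trajectories, batch and cell-composition structure, smoking signals and
    Weibull-baseline survival, so the full pipeline can be exercised and
    tested without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    glmnet,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
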