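Package: radage
Title: Radiation-Age Association Analysis for Blood Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for associating chronological age with ionizing
    radiation exposure in processed blood gene-expression cohorts. Determines an
    empirical young/old age threshold by scanning candidate cutoffs with per-gene
    t-tests and balanced-subsampling ROC AUC, runs two-group differential
    expression across radiation dose bins with Benjamini-Hochberg FDR control,
    screens genes for age-by-radiation interactions with per-gene linear models,
    exports preranked gene lists, and evaluates candidate genes on a lung-disease
    cohort with one-vs-rest contrasts, a cross-split candidate filter, and a
    three-way disease-by-ethnicity-by-sex interaction model. Includes a synthetic
    cohort generator so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
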