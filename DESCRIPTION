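Package: exprAttributor
Title: Attribution of Target-Gene Expression to Transcription-Factor
    Activity, Somatic Mutations and miRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how much of a target gene's per-patient mRNA
    expression (CD274/PD-L1 in the motivating application) is explained by
    transcription-factor activity, using regulon-based activity proxies and
    sign-constrained (bounded-variable least squares) multiple linear
    regression with significance-driven variable selection.  Patients whose
    observed expression deviates more than a fold threshold from the model
    prediction are stratified into under- and over-predicted groups, and
    high unexplained expression is attributed to somatic mutations in
    critical genes (prevalence / fold-change / Mann-Whitney filters) or to
    low abundance of critical miRNAs (negative Pearson screen and quantile
    assignment).  A synthetic-cohort generator with recorded ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'prediction-classes.R'
    'bvls.R'
    'regression.R'
    'attribution.R'
    'cohort-io.R'
    'exprAttributor-package.R'
    'mirna-explanation.R'
    'mutation-explanation.R'
    'tf-activity.R'
    'pipeline.R'
    'synthetic-cohort.R'
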