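Package: radsig
Title: Radioresistance Gene-Signature Discovery and Single-Sample
    Enrichment Scoring for HPV-Negative Head and Neck Cancer
Version: 0.1.0
Authors@R:
    person("radsig", "maintainers", email = "radsig@example.org",
           role = c("aut", "cre"))
Description: Implements a three-stage gene-selection funnel for discovering
    radioresistance-associated gene signatures in HPV-negative head and neck
    squamous cell carcinoma (paired tumour-versus-normal differential
    expression, radioresistant-versus-radiosensitive cell-line two-way ANOVA,
    and per-gene multivariate Cox screening), together with a single-sample
    gene-set enrichment (ssGSEA) engine that turns a directional signature
    into a per-sample radioresistance (RadR) score.  Downstream tools cover
    median-split survival stratification, molecular-subtype and genotype
    group comparisons, and correlation screens against hallmark enrichment,
    protein-expression and drug-IC50 panels.  A synthetic-cohort generator
    with known ground truth stands in for the public tumour and cell-line
    datasets, so that every stage of the pipeline is testable offline.
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
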