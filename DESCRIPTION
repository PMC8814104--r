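Package: phenorisk
Title: Ontology-Based Phenotypic Risk Stratification for Congenital Heart Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Risk stratification of complex congenital heart disease cohorts
    from Human Phenotype Ontology (HPO) annotations. Parses OBO ontologies,
    computes Resnik information content and symmetric best-match-average
    patient similarity, clusters patients by complete-linkage hierarchical
    clustering of the similarity-derived distance matrix, characterizes the
    phenotype distribution of each cluster, and compares cluster prognosis
    with Kaplan-Meier curves, log-rank tests, landmark analysis and Cox
    proportional hazards regression with Benjamini-Hochberg adjustment.
    Includes a synthetic-cohort generator with planted cluster structure and
    a piecewise-exponential hazard changepoint for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
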