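Package: cytoallergy
Title: Filter-Then-Classify Evaluation of Cytokine and Clinical Predictors of Childhood Allergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate predictive models of allergy development in
    birth cohorts from stimulated-cytokine panels and clinical variables.
    Implements the full analysis pipeline: Luminex-style preprocessing
    (background subtraction, inter-plate positive-control QC, sparse-feature
    removal, leakage-aware class-conditional imputation), per-variable
    two-group testing with Benjamini-Hochberg correction, a clinical kernel
    for mixed-type variables, and a repeated random subsampling protocol
    (filter-then-classify with Random Forest, kernel SVM and 1-nearest
    neighbour) scored by the Balanced Classification Rate with
    Nadeau-corrected confidence intervals. A synthetic cohort generator
    reproduces the data structure of a cytokine birth-cohort study
    (class imbalance, a 288-condition cytokine grid, blockwise missingness)
    so the pipeline is fully testable without patient-level data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    yaml,
    randomForest,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
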