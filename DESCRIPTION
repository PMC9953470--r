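Package: torsadeNet
Title: In Silico Torsade-de-Pointes Risk Assessment from Action Potential Shapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A proarrhythmic (torsade-de-pointes) risk pipeline for drug
    candidates. Ion-channel dose-response tables are fitted to Hill curves
    and bootstrapped to quantify experimental uncertainty; drug-blocked
    ventricular action potentials are simulated with the O'Hara-Rudy human
    ventricular myocyte model under the Dutta conductance optimization and
    slow (bradycardic) pacing; action-potential shapes are assembled into
    labeled datasets; a compact one-dimensional convolutional neural network
    classifies torsade risk into high, intermediate and low classes; and the
    classifier is evaluated with repeated resampled testing (per-class AUC,
    sensitivity, specificity and likelihood ratios with percentile
    confidence intervals). Seeded synthetic generators make every stage
    runnable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'torsadeNet-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'panel-methods.R'
    'hill.R'
    'io.R'
    'ord.R'
    'apmetrics.R'
    'dataset.R'
    'cnn.R'
    'riskeval.R'
    'synth.R'
    'pipeline.R'
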