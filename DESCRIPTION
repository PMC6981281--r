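Package: necrokinetics
Title: Discrete-Cycle Kinetics of Neuronal Active Necrosis and CSF Biomarker
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the time course of active neuronal necrosis in
    neurodegeneration as a discrete-cycle geometric decay process: in each
    cycle of fixed period a constant fraction of the residual neuron
    population dies, so per-field death counts rise to a peak after onset and
    then decay geometrically. Provides closed-form evaluation of residual
    neurons and deaths per cycle, deterministic grid-search least-squares
    fitting of the four model parameters from per-field count time courses,
    prediction at unmeasured time points, and bootstrap confidence intervals.
    Also implements the accompanying biomarker-discrimination toolkit
    (Wilcoxon rank-sum test with exact and tie-corrected normal p-values,
    Bonferroni adjustment, empirical ROC curves and AUC, Pearson correlation,
    box-plot summaries) and seeded synthetic-data generators for Poisson or
    negative-binomial count fields and log-normal biomarker cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'necrosis-model.R'
    'model-fitting.R'
    'synthetic-data.R'
    'biomarker-stats.R'
    'io.R'
    'pipeline.R'
    'utils.R'
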