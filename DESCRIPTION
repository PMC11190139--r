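Package: laminarq
Title: Laminar Quantitative MRI Simulation and Case-Control Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for depth-resolved quantitative
    MRI of the cortex at ultra-high field. Implements the MP2RAGEME
    steady-state signal model with lookup-table T1 estimation and
    least-squares multi-echo T2* fitting, synthetic cortical-slab phantoms
    with known laminar ground truth and cohort-level effect calibration,
    distance-based cortical depth fields with 10-depth profile extraction
    inside refined regions of interest, profile parameterization (global
    mean, polynomial area under the curve, white/gray-matter boundary
    offset), and a case-control inference harness (ANCOVA with age and sex
    covariates, Kendall rank correlations with bootstrap confidence
    intervals, lateralization and within-patient analyses).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'mp2rageme.R'
    'phantom.R'
    'cohort.R'
    'laminar.R'
    'profile-metrics.R'
    'stats.R'
    'pipeline.R'
    'io.R'
    'laminarq-package.R'
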