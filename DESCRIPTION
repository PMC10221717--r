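Package: dropletTiter
Title: Droplet Digital PCR Quantification and Single-Cell Infectious Titer Estimation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Partition-Poisson quantification for droplet digital PCR (ddPCR)
    assays of viral preparations, together with a synthetic droplet-data
    generator that emulates genome partitioning, whole-cell encapsulation,
    MOI-driven infection and free-floating RNA contamination. Implements
    single-target concentration estimation from positive/negative droplet
    counts (Poisson MLE with Wilson confidence intervals), duplex two-virus
    quantification, the linkage (excess double-positive) statistic for
    cell-mediated co-occurrence of a housekeeping and a viral target, and two
    single-cell infectious-titer estimators based on double-positive droplet
    counting and on linkage, with end-to-end scenario runners for
    dilution-series, virus-mixture and infected-cell experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: ddPCR, Software, StatisticalMethod, SingleCell
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'conditions.R'
    'dropletTiter-package.R'
    'quant-core.R'
    'duplex-linkage.R'
    'io.R'
    'methods-accessors.R'
    'sim-droplets.R'
    'titer-estimators.R'
    'workflows.R'
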