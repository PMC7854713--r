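Package: ernaclock
Title: Decay Kinetics of Environmental DNA and RNA and the eRNA:eDNA Age
    Clock
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of environmental DNA (eDNA)
    and RNA (eRNA) release and degradation in mesocosm experiments.
    Implements first-order exponential decay inference on qPCR copy-number
    time series with detection-limit censoring, half-life confidence
    intervals from decay constants, standard-curve quantification (Cq to
    copies, amplification efficiency), mixed-effect and two-stage decay
    estimators with abundance effects and multiplicity-adjusted contrasts,
    short:long fragment and eRNA:eDNA ratio regressions, and an age
    estimator that inverts the eRNA:eDNA ratio decay into time since
    release with bootstrap uncertainty. A synthetic mesocosm generator
    reproduces the statistical structure of a dreissenid mussel tank
    experiment so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'constructors.R'
    'ernaclock-package.R'
    'kinetics.R'
    'inference.R'
    'io.R'
    'qpcr.R'
    'simulate.R'
    'ratio.R'
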