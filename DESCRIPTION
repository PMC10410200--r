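Package: reactfc
Title: Molecular-Enriched Functional Connectivity by Dual Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates transporter- and receptor-enriched functional
    connectivity from 4-D BOLD volumes by two-stage dual regression against
    molecular density templates (REACT), with template conditioning and
    collinearity screening, permutation-based cluster-extent family-wise
    error inference for 2x4 within-subject factorial designs, Sidak-corrected
    post-hoc contrasts, and a seeded synthetic-study generator with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'templates.R'
    'react.R'
    'anova.R'
    'clusters.R'
    'posthoc.R'
    'simulate.R'
    'pipeline.R'
    'reactfc-package.R'
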