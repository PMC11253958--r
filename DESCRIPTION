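Package: iohexolGFR
Title: Measured GFR from Iohexol Plasma Clearance with Simplified Protocols
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes measured glomerular filtration rate (GFR) from iohexol
    plasma concentration-time data under the reference two-compartment
    protocol and shortened one-compartment (slope-intercept) protocols with
    Brochner-Mortensen correction, together with serum-creatinine eGFR
    equations (CKD-EPI 2009, IDMS-traceable MDRD) and a full
    method-agreement toolkit for repeated-measures comparisons: Lin's
    concordance correlation coefficient, total deviation index, coverage
    probability, P10/P15, Bland-Altman limits, mountain plots,
    random-intercept regression and patient-clustered bootstrap confidence
    intervals. A synthetic chronic-kidney-disease cohort generator with
    two-compartment iohexol kinetics makes the whole pipeline testable
    without patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    lme4,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
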