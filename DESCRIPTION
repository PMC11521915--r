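Package: blendedpay
Title: Blended Provider-Payment Simulation for District Hospitals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and simulating a blended provider-payment
    framework for public-sector district hospitals: a risk-adjusted global
    budget for outpatient care fitted by ordinary least squares on district
    demand- and supply-side indicators, a case-based bundled payment for
    inpatient care priced through health-benefit-package tariffs and
    specialty-level weighted costs, and a per-bed global budget for indirect
    services. Includes a tier-stratified multivariate-normal synthetic data
    generator emulating a facility costing survey, upgrade scenarios
    (public-health staffing standards and medical-college conversion),
    national budget-impact rollups, and comparison against actual
    expenditure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    car,
    jsonlite,
    lmtest,
    nortest,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
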