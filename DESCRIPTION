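Package: gpdiffuse
Title: System Dynamics Model of GP Contract-Service Diffusion in
    Occupational Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stock-and-flow simulation of general practitioner (GP)
    contract-service adoption among a young and middle-aged occupational
    population, built on an extended Bass diffusion model. Adoption is
    driven by GP team mobilization and by word-of-mouth modulated by
    demand-side attractiveness (service-package contents), supply-side
    driving force (incentive policies with an income lookup), and a
    collaborative income-distribution effect within GP teams. Includes a
    scenario engine for intervention experiments, inverse calibration of
    the parameter vector against reported 2030 outcomes, a synthetic
    historical-series generator, historicity and sensitivity validation,
    and configuration/result serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
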