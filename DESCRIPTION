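Package: organflow
Title: Flow Pharmacokinetics, Design and Inference for Multi-Organ
    Microfluidic Culture Platforms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Well-mixed compartmental mass-balance modelling of perfused
    multi-organ microfluidic culture platforms (single-tissue, two-tissue
    and five-tissue presets). Simulates hormone distribution through
    donor, tissue and acceptor modules under through-system and
    recirculating flow; generates 28-day menstrual-cycle endocrine
    forcing and ovarian secretion profiles (cyclic and pregnancy-like
    modes) with a realistic daily immunoassay sampling model (lognormal
    noise, left-censoring at functional sensitivity); searches flow-rate
    and volume grids against physiologic-concentration and response-time
    constraints; recovers secretion rates from noisy censored effluent
    series; and applies pump and actuator quality-control rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
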