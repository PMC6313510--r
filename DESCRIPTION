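Package: crewsim
Title: Hybrid System-Dynamics and Agent-Based Simulation of Safety-Violation
    Contagion in Construction Crews
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A cell-based virtual construction site simulator in which worker
    agents decide between compliant task execution and routine or situational
    safety violations via risk-homeostasis safety checking, managers inspect
    and intervene within a limited distance, and crew-level social contagion
    of hazard tolerance follows memory-weighted adaptation equations. A daily
    system-dynamics layer (perceived social support, production pressure,
    attitudinal ambivalence, safety control pressure) re-parameterizes the
    agents, closing the feedback loop. Includes baseline validation,
    one-at-a-time sensitivity analysis, and a replicated 2^4 factorial
    experiment engine with standardized-effect (Pareto) analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
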