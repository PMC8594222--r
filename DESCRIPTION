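Package: tisim
Title: Tumor-Immune System Modelling of Combined 5-FU and Anti-CD25 Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Ordinary-differential-equation model of pancreatic tumor-immune
    system dynamics under 5-fluorouracil chemotherapy and anti-CD25
    immunotherapy. Provides the calibrated six-equation model (with
    quasi-steady-state cytokines) and its nine-equation parent, stiff-capable
    simulation with pulsed treatment forcing, NRMSE goodness of fit with
    genetic-algorithm parameter estimation, Bliss combination-index synergy
    analysis, genetic-algorithm optimization of injection schedules,
    triangular-fuzzy uncertainty propagation by alpha-cuts, and global
    sensitivity analysis (Latin hypercube sampling with partial rank
    correlation coefficients, and Morris elementary effects).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
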