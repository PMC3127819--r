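Package: pflswitch
Title: Dynamics, Bistability and Parameter Inference for an Inducible
    Transcriptional Positive Feedback Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation models of a Tet-OFF inducible
    transcriptional positive feedback loop (PFL) and its open-loop control
    (NOPFL) stably integrated in mammalian cells.  Provides stiff-solver
    switch-off simulations started from the ON steady state, switch-off-time
    statistics from fluorescence time-courses, exponential half-life
    estimation for destabilised reporters, nullcline/equilibrium/bistability
    analysis with basin-of-attraction mapping, joint multistart trust-region
    parameter estimation in log space against replicate time-courses, and a
    seeded synthetic-data generator emulating time-lapse microscopy
    switch-off experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
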